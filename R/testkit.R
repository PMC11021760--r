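# Synthetic toy complexes: a shell of real (minimal) residues placed at
# ideal interaction geometry around a planted ligand pose, so hotspot
# typing, scoring, growth and the regrow benchmark run end-to-end with no
# external structure files. Everything is regenerable from (seed, parameters).

# --- internal-coordinate residue templates -------------------------------

# NeRF-style placement: position D bonded to C with |CD| = r, angle(D,C,B)
# = theta (deg) and dihedral(D,C,B,A) = phi (deg).
.nerf <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- unit(C - B)
  n <- unit(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Template coordinates for a minimal residue, with standard PDB atom names.
# Returns tibble(atom_name, element, x, y, z).
residue_template <- function(resname) {
  xyz <- list()
  put <- function(name, el, pos) xyz[[name]] <<- list(el = el, p = pos)
  theta_c <- 110.4 * pi / 180
  put("N", "N", c(0, 0, 0))
  put("CA", "C", c(1.458, 0, 0))
  # CA->C direction makes the backbone angle with CA->N, in the xy plane
  put("C", "C", c(1.458, 0, 0) + 1.525 * c(cos(pi - theta_c), sin(pi - theta_c), 0))
  A <- function(nm) xyz[[nm]]$p
  put("O", "O", .nerf(A("N"), A("CA"), A("C"), 1.231, 120.8, 180))
  put("H", "H", .nerf(A("C"), A("CA"), A("N"), 1.010, 118.2, 180))
  if (resname %in% c("SER", "PHE", "LYS", "ASP", "TYR")) {
    put("CB", "C", .nerf(A("C"), A("N"), A("CA"), 1.530, 110.5, -122))
  }
  if (resname == "SER") {
    put("OG", "O", .nerf(A("N"), A("CA"), A("CB"), 1.417, 110.8, 180))
    put("HG", "H", .nerf(A("CA"), A("CB"), A("OG"), 0.967, 108.5, 180))
  } else if (resname == "PHE") {
    put("CG", "C", .nerf(A("N"), A("CA"), A("CB"), 1.510, 114.0, 180))
    put("CD1", "C", .nerf(A("CA"), A("CB"), A("CG"), 1.390, 120.0, 90))
    put("CD2", "C", .nerf(A("CA"), A("CB"), A("CG"), 1.390, 120.0, 270))
    put("CE1", "C", .nerf(A("CB"), A("CG"), A("CD1"), 1.390, 120.0, 180))
    put("CE2", "C", .nerf(A("CB"), A("CG"), A("CD2"), 1.390, 120.0, 180))
    put("CZ", "C", .nerf(A("CG"), A("CD1"), A("CE1"), 1.390, 120.0, 0))
  } else if (resname == "LYS") {
    put("CG", "C", .nerf(A("N"), A("CA"), A("CB"), 1.520, 112.0, 180))
    put("CD", "C", .nerf(A("CA"), A("CB"), A("CG"), 1.520, 112.0, 180))
    put("CE", "C", .nerf(A("CB"), A("CG"), A("CD"), 1.520, 112.0, 180))
    put("NZ", "N", .nerf(A("CG"), A("CD"), A("CE"), 1.489, 112.0, 180))
    put("HZ1", "H", .nerf(A("CD"), A("CE"), A("NZ"), 1.010, 109.5, 60))
    put("HZ2", "H", .nerf(A("CD"), A("CE"), A("NZ"), 1.010, 109.5, 180))
    put("HZ3", "H", .nerf(A("CD"), A("CE"), A("NZ"), 1.010, 109.5, 300))
  } else if (resname == "TYR") {
    put("CG", "C", .nerf(A("N"), A("CA"), A("CB"), 1.510, 114.0, 180))
    put("CD1", "C", .nerf(A("CA"), A("CB"), A("CG"), 1.390, 120.0, 90))
    put("CD2", "C", .nerf(A("CA"), A("CB"), A("CG"), 1.390, 120.0, 270))
    put("CE1", "C", .nerf(A("CB"), A("CG"), A("CD1"), 1.390, 120.0, 180))
    put("CE2", "C", .nerf(A("CB"), A("CG"), A("CD2"), 1.390, 120.0, 180))
    put("CZ", "C", .nerf(A("CG"), A("CD1"), A("CE1"), 1.390, 120.0, 0))
    put("OH", "O", .nerf(A("CD1"), A("CE1"), A("CZ"), 1.375, 120.0, 180))
    put("HH", "H", .nerf(A("CE1"), A("CZ"), A("OH"), 0.967, 109.0, 90))
  } else if (resname == "ASP") {
    put("CG", "C", .nerf(A("N"), A("CA"), A("CB"), 1.520, 112.6, 180))
    put("OD1", "O", .nerf(A("CA"), A("CB"), A("CG"), 1.250, 118.5, 90))
    put("OD2", "O", .nerf(A("CA"), A("CB"), A("CG"), 1.250, 118.5, 270))
  }
  tibble::tibble(
    atom_name = names(xyz),
    element = vapply(xyz, function(z) z$el, character(1)),
    x = vapply(xyz, function(z) z$p[1], numeric(1)),
    y = vapply(xyz, function(z) z$p[2], numeric(1)),
    z = vapply(xyz, function(z) z$p[3], numeric(1))
  )
}

# Interaction anchor of a template: anchor atom(s) and the outgoing
# interaction direction in template coordinates.
.template_anchor <- function(resname, tpl) {
  p <- function(nm) as.numeric(tpl[tpl$atom_name == nm, c("x", "y", "z")])
  switch(resname,
    SER = list(anchor = p("OG"), dir = unit(p("HG") - p("OG"))),            # donor O-H
    GLY = list(anchor = p("O"), dir = unit(p("O") - p("C"))),               # acceptor C=O
    LYS = list(anchor = p("NZ"), dir = unit(p("HZ1") - p("NZ"))),           # donor N-H (+)
    TYR = list(anchor = p("OH"), dir = unit(p("HH") - p("OH"))),            # donor O-H
    ASP = list(anchor = p("OD1"), dir = unit(p("OD1") - p("CG"))),          # acceptor (-)
    PHE = {
      ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
      M <- as.matrix(tpl[match(ring, tpl$atom_name), c("x", "y", "z")])
      ctr <- colMeans(M)
      sv <- svd(sweep(M, 2, ctr))
      n3 <- unit(sv$v[, 3])
      # point the interaction normal away from the backbone so the stacked
      # partner's backbone ends up on the far side of the ligand
      ca <- p("CA")
      if (sum(n3 * (ca - ctr)) > 0) n3 <- -n3
      list(anchor = ctr, dir = n3)
    },
    stop("no template anchor for ", resname))
}

# Rigidly place a template so its anchor sits at `target` with its
# interaction direction along `dir_target`; the spin about the axis is
# chosen on a deterministic grid to keep the residue clear of the ligand
# (first `n_core` avoid rows) and, more loosely, of other residues —
# proteins pack against each other far closer than against the ligand.
.place_residue <- function(resname, target, dir_target, avoid_xyz, avoid_el,
                           spin_offset = 0, n_core = nrow(avoid_xyz)) {
  tpl <- residue_template(resname)
  anc <- .template_anchor(resname, tpl)
  M <- as.matrix(tpl[, c("x", "y", "z")])
  R1 <- .rotation_between(anc$dir, dir_target)
  M1 <- sweep(sweep(M, 2, anc$anchor) %*% t(R1), 2, target, "+")
  vr_res <- vdw_radius(tpl$element)
  best <- NULL; best_score <- -Inf; best_lig <- -Inf; best_res <- -Inf
  for (ang in (spin_offset + seq(0, 330, by = 30)) * pi / 180) {
    M2 <- rotate_about_axis(M1, dir_target, target, ang)
    heavy <- tpl$element != "H"
    if (nrow(avoid_xyz)) {
      d <- sqrt(outer(rowSums(M2[heavy, , drop = FALSE]^2), rowSums(avoid_xyz^2), "+") -
                  2 * M2[heavy, , drop = FALSE] %*% t(avoid_xyz))
      r0 <- outer(vr_res[heavy], vdw_radius(avoid_el), "+")
      ratios <- d / r0
      m_lig <- min(ratios[, seq_len(n_core), drop = FALSE])
      m_res <- if (n_core < ncol(ratios)) {
        min(ratios[, (n_core + 1):ncol(ratios), drop = FALSE])
      } else Inf
    } else { m_lig <- Inf; m_res <- Inf }
    score <- min(m_lig, m_res + 0.15)
    if (score > best_score) {
      best_score <- score; best <- M2; best_lig <- m_lig; best_res <- m_res
    }
    if (m_lig >= 0.8 && m_res >= 0.65) break  # comfortably placed
  }
  tpl$x <- best[, 1]; tpl$y <- best[, 2]; tpl$z <- best[, 3]
  list(tpl = tpl, margin = best_lig, margin_res = best_res)
}

#' Build a deterministic toy protein-ligand complex
#'
#' Embeds the ligand (its "crystal" pose), fragments it with
#' [fragment_ligand()], and for every fragment places a complementary
#' minimal residue at ideal interaction geometry: a lysine ammonium
#' donating to a ligand acceptor or an aspartate carboxylate accepting from
#' a ligand donor; one fragment additionally gets a phenylalanine ring
#' stacked on its aromatic ring, which pins the rotational mode that two
#' point anchors alone leave free. Additional glycine shell residues give
#' the pocket steric body, their backbone polar groups oriented outward. The result exercises hotspot
#' typing, probe placement, growth and the pose-reproduction benchmark with
#' no external files.
#'
#' @param ligand_smiles SMILES of the planted ligand (2-3 fragments works
#'   best; every fragment should carry a donor, acceptor or aromatic ring).
#' @param seed integer seed; the complex is bitwise reproducible from it.
#' @param n_shell extra glycine shell residues (steric body).
#' @param hb_dist,ar_dist planted interaction distances (angstroms).
#' @return an `fg_toy`: list with `protein` (`fg_protein`), `ligand`
#'   (molecule with the crystal pose as conformer 1), `fragments`
#'   (from [fragment_ligand()]), `planted` (tibble of planted interactions),
#'   and `seed`.
#' @export
make_toy_complex <- function(ligand_smiles, seed = 1L, n_shell = 2L,
                             hb_dist = 2.9, ar_dist = 3.8) {
  mol <- parse_molecule(ligand_smiles)
  mol <- embed_molecule(mol, seed = derive_seed(seed, "ligand"))
  xyz <- mol$conformers[[1]]
  xyz <- sweep(xyz, 2, colMeans(xyz[heavy_atoms(mol), , drop = FALSE]))
  mol$conformers <- list(xyz)
  frags <- fragment_ligand(mol)
  feats <- ligand_features(mol, xyz)
  placed <- list()
  planted <- list()
  avoid_xyz <- xyz[heavy_atoms(mol), , drop = FALSE]
  avoid_el <- mol$atoms$element[heavy_atoms(mol)]
  n_lig <- nrow(avoid_xyz)
  resno <- 0L

  ring_planted <- FALSE
  pick_features <- function(src_atoms) {
    # one hydrogen-bond partner per fragment (acceptor preferred over
    # donor). Exactly one fragment additionally gets an aromatic stacking
    # partner: two point anchors alone leave the ligand free to roll about
    # their axis, and the stacked ring pins that rotational mode so the
    # planted pose is uniquely determined by its interactions.
    hb <- NA_integer_
    for (kd in c("hb_acceptor", "hb_donor")) {
      rowsk <- which(feats$kind == kd)
      for (r in rowsk) {
        if (feats$atom[r] %in% src_atoms) { hb <- r; break }
      }
      if (!is.na(hb)) break
    }
    ring <- NA_integer_
    if (!ring_planted) {
      for (r in which(feats$kind == "aromatic_ring")) {
        ctr <- as.numeric(feats[r, c("x", "y", "z")])
        d <- sqrt(rowSums(sweep(xyz[src_atoms, , drop = FALSE], 2, ctr)^2))
        if (sum(d < 1.6) >= 5) { ring <- r; break }
      }
    }
    if (!is.na(ring)) ring_planted <<- TRUE
    c(hb, ring)
  }

  add_residue <- function(resname, anchor_pos, dir_out, spin_offset, dists) {
    # try each anchor distance until the residue is clear of the ligand and
    # reasonably packed against the other residues
    best <- NULL
    ok <- function(pl) pl$margin >= 0.75 && pl$margin_res >= 0.62
    for (dd in dists) {
      pl <- .place_residue(resname, anchor_pos + dir_out * dd, -dir_out,
                           avoid_xyz, avoid_el, spin_offset, n_core = n_lig)
      if (is.null(best) || min(pl$margin, pl$margin_res + 0.15) >
            min(best$margin, best$margin_res + 0.15)) best <- pl
      if (ok(pl)) { best <- pl; break }
    }
    if (!ok(best)) {
      warning(resname, " partner could not be placed clash-free (ligand margin ",
              round(best$margin, 2), ", residue margin ",
              round(best$margin_res, 2), "); skipped")
      return(NA_integer_)
    }
    resno <<- resno + 1L
    tpl <- best$tpl
    tpl$resname <- resname; tpl$resno <- resno
    placed[[length(placed) + 1L]] <<- tpl
    avoid_xyz <<- rbind(avoid_xyz, as.matrix(tpl[tpl$element != "H", c("x", "y", "z")]))
    avoid_el <<- c(avoid_el, tpl$element[tpl$element != "H"])
    resno
  }

  withr::with_seed(derive_seed(seed, "placement"), {
    for (fi in seq_along(frags)) {
      src <- frags[[fi]]$src_atoms
      picked <- pick_features(src)
      if (all(is.na(picked))) {
        warning("fragment ", fi, " has no usable pharmacophore feature; no residue planted")
        next
      }
      for (r in picked[!is.na(picked)]) {
      fpos <- as.numeric(feats[r, c("x", "y", "z")])
      fdir <- as.numeric(feats[r, c("dx", "dy", "dz")])
      kind <- feats$kind[r]
      spin <- stats::runif(1, 0, 30)
      if (kind == "hb_acceptor") {
        # lysine ammonium donates to the ligand acceptor; the backbone
        # sits four bonds away from the site
        rn <- add_residue("LYS", fpos, fdir, spin, hb_dist)
        if (!is.na(rn)) planted[[length(planted) + 1L]] <- tibble::tibble(
          fragment = fi, kind = "hb_donor", resno = rn, feature_atom = feats$atom[r])
      } else if (kind == "hb_donor") {
        # aspartate carboxylate accepts from the ligand donor
        rn <- add_residue("ASP", fpos, fdir, spin, hb_dist)
        if (!is.na(rn)) planted[[length(planted) + 1L]] <- tibble::tibble(
          fragment = fi, kind = "hb_acceptor", resno = rn, feature_atom = feats$atom[r])
      } else {
        # stack the partner ring on whichever ring face is clear of the
        # rest of the ligand (the twisted neighboring ring usually blocks
        # one face), backing off along the normal if needed
        rn <- NA_integer_
        for (face in list(fdir, -fdir)) {
          rn <- suppressWarnings(
            add_residue("PHE", fpos, face, spin,
                        c(ar_dist, ar_dist + 0.3, ar_dist + 0.6)))
          if (!is.na(rn)) break
        }
        if (is.na(rn)) warning("PHE partner could not be placed clash-free; skipped")
        if (!is.na(rn)) planted[[length(planted) + 1L]] <- tibble::tibble(
          fragment = fi, kind = "aromatic_ring", resno = rn, feature_atom = NA_integer_)
      }
      }
    }
    if (!length(planted)) stop("unusable fixture: no hotspot could be planted")
    # glycine shell for pocket body
    ctr <- colMeans(xyz[heavy_atoms(mol), , drop = FALSE])
    tries <- 0L
    added <- 0L
    while (added < n_shell && tries < 40L) {
      tries <- tries + 1L
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      # shell residues give the pocket steric body; their carbonyl anchor is
      # oriented outward (away from the ligand) so the backbone polar groups
      # do not compete with the planted interaction sites
      target <- ctr + u * stats::runif(1, 8.0, 9.5)
      pl <- .place_residue("GLY", target, u, avoid_xyz, avoid_el,
                           stats::runif(1, 0, 30), n_core = n_lig)
      if (pl$margin < 0.85 || pl$margin_res < 0.7) next
      resno <- resno + 1L
      tpl <- pl$tpl; tpl$resname <- "GLY"; tpl$resno <- resno
      placed[[length(placed) + 1L]] <- tpl
      avoid_xyz <- rbind(avoid_xyz, as.matrix(tpl[tpl$element != "H", c("x", "y", "z")]))
      avoid_el <- c(avoid_el, tpl$element[tpl$element != "H"])
      added <- added + 1L
    }
  })

  atoms <- dplyr::bind_rows(placed)
  atoms <- tibble::tibble(
    element = atoms$element, resname = atoms$resname, resno = atoms$resno,
    chain = "A", insert = "", atom_name = atoms$atom_name,
    x = atoms$x, y = atoms$y, z = atoms$z,
    reskey = paste0("A:", atoms$resno)
  )
  protein <- structure(list(atoms = atoms, hetatm = atoms[0, ], source = "<toy>"),
                       class = "fg_protein")
  structure(list(protein = protein, ligand = mol, fragments = frags,
                 planted = dplyr::bind_rows(planted), seed = seed,
                 smiles = canonical_smiles(mol)),
            class = "fg_toy")
}

#' @export
print.fg_toy <- function(x, ...) {
  cat(sprintf("<toy complex: ligand %s, %d residues, %d planted hotspots>\n",
              x$smiles, length(unique(x$protein$atoms$resno)), nrow(x$planted)))
  invisible(x)
}

#' Write a toy complex to disk (PDB + SDF + fragment library)
#'
#' @param toy an `fg_toy`.
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_toy_complex <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, "protein.pdb")
  sdf <- file.path(dir, "ligand.sdf")
  lib <- file.path(dir, "library.smi")
  write_protein(toy$protein, pdb)
  writeLines(mol_to_molblock(toy$ligand, conformer = 1, title = "planted_ligand"), sdf)
  writeLines(vapply(toy$fragments, function(f) {
    paste(canonical_smiles(f$mol), if (f$role == "linker") "linker" else "")
  }, character(1)), lib)
  list(protein = pdb, ligand = sdf, library = lib)
}

# Decoy pool for library construction: small, MCF-clean rings and chains.
.DECOY_POOL <- c(
  "C1CCCCC1", "C1CCCC1", "C1CCOC1", "C1CCNC1", "CC(C)C", "CCC", "CCO",
  "CCOC", "CCN", "C1CCNCC1", "C1CCOCC1", "CC(C)O", "CCCC", "CC(C)N"
)

#' Build a fragment library of true fragments plus decoys
#'
#' @param include list of molecules or `fg_fragment`s that must be present
#'   (the "true" fragments).
#' @param n_decoys number of decoys drawn from a fixed pool of small rings
#'   and chains (all of which pass the core filter rules).
#' @param seed shuffle seed.
#' @return list of `fg_fragment`s, deterministically shuffled.
#' @export
make_fragment_library <- function(include, n_decoys = 10L, seed = 1L) {
  trues <- lapply(include, function(x) {
    if (inherits(x, "fg_fragment")) x else fragment(x)
  })
  pool <- .DECOY_POOL
  decoys <- list()
  withr::with_seed(derive_seed(seed, "library"), {
    pick <- rep_len(sample(pool), max(n_decoys, 0))
    for (i in seq_len(n_decoys)) {
      dm <- parse_molecule(pick[i])
      # decoys carry a single designated attachment point, as curated
      # building-block libraries typically do
      decoys[[i]] <- fragment(dm, attachment = enumerate_attachment_points(dm)[1],
                              id = paste0("decoy", i))
    }
    all_frags <- c(trues, decoys)
    all_frags[sample(length(all_frags))]
  })
}
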