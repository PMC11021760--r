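# Probe placement: enumerate geometric pairings of probe pharmacophore
# features with complementary pocket hotspots, refine poses rigidly, and
# select the starting set for growth.

# Rotation taking unit vector a onto unit vector b.
.rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- cross3(a, b)
  s <- sqrt(sum(v^2)); c0 <- sum(a * b)
  if (s < 1e-9) {
    if (c0 > 0) return(diag(3))
    # opposite vectors: rotate 180 deg about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(cross3(a, p))
    return(rotation_from_vector(ax * pi))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c0) / s^2)
}

# Hard-clash test used at placement time: any ligand heavy atom closer than
# `ratio` times the vdW sum to a pocket heavy atom.
has_hard_clash <- function(lig_xyz, lig_el, pocket, ratio = 0.7) {
  patoms <- pocket_atoms(pocket)
  patoms <- patoms[patoms$element != "H", , drop = FALSE]
  if (!nrow(patoms)) return(FALSE)
  pxyz <- cbind(patoms$x, patoms$y, patoms$z)
  d2 <- outer(rowSums(lig_xyz^2), rowSums(pxyz^2), "+") - 2 * lig_xyz %*% t(pxyz)
  d <- sqrt(pmax(d2, 0))
  r0 <- outer(vdw_radius(lig_el), vdw_radius(patoms$element), "+")
  any(d < ratio * r0)
}

# Pharmacophore score of a pose: sum over hotspots of kind weight times the
# best switch value achieved (the matched hotspots are those with g > 0).
pharmacophore_score <- function(mol, xyz, hotspots, model) {
  feats <- ligand_features(mol, xyz)
  ct <- contact_table(feats, hotspots, model)
  if (!nrow(ct)) return(list(score = 0, matched = integer()))
  agg <- stats::aggregate(g ~ hotspot, data = ct, FUN = max)
  w <- model$kind_weights[hotspots$kind[agg$hotspot]]
  list(score = sum(w * agg$g), matched = sort(agg$hotspot))
}

#' Enumerate probe placements at pocket hotspots
#'
#' For every probe conformer and every geometrically feasible pairing of a
#' probe pharmacophore feature with a complementary hotspot (ligand acceptor
#' with donor hotspot, ligand donor with acceptor hotspot, ring with ring),
#' poses are constructed at ideal pairing geometry and spun about the pairing
#' axis on a fixed angular grid. Poses with a hard heavy-atom clash
#' (closer than `clash_ratio` times the vdW sum to the protein) are
#' discarded. Output is sorted by pharmacophore score (descending), then
#' binding energy (ascending).
#'
#' @param probe the probe molecule.
#' @param pocket an `fg_pocket`.
#' @param hotspots hotspot tibble.
#' @param model energy model.
#' @param n_conformers probe conformers to try.
#' @param seed conformer seed.
#' @param n_orientations rotations about the pairing axis per pairing.
#' @param clash_ratio hard-clash threshold (default 0.7).
#' @return tibble of probe poses: `mol` and `pose` list-columns,
#'   `pharmacophore_score`, `binding_energy`, `matched` (hotspot indices),
#'   `conformer`, `hotspot`, `orientation`.
#' @export
enumerate_probe_placements <- function(probe, pocket, hotspots,
                                       model = default_energy_model(),
                                       n_conformers = 3L, seed = 1L,
                                       n_orientations = 6L, clash_ratio = 0.7) {
  stopifnot(n_conformers >= 1)
  confs <- generate_conformers(probe, n = n_conformers, seed = seed)
  hv <- heavy_atoms(probe)
  el <- probe$atoms$element[hv]
  rows <- list()
  # rotation-invariant containment envelope: poses must stay within the
  # pocket sphere (max atom distance from the pocket centroid) plus 3 A
  pocket_r <- {
    pxyz <- protein_xyz(pocket$protein, pocket$atom_idx)
    sqrt(max(rowSums(sweep(pxyz, 2, pocket$centroid)^2)))
  }
  for (ci in seq_along(confs)) {
    xyz0 <- confs[[ci]]
    feats <- ligand_features(probe, xyz0)
    feats <- feats[feats$kind %in% c("hb_donor", "hb_acceptor", "aromatic_ring"), , drop = FALSE]
    if (ci == 1 && !nrow(feats)) {
      stop("unplaceable probe: no pharmacophore feature (donor/acceptor/aromatic)")
    }
    for (h in seq_len(nrow(hotspots))) {
      hk <- hotspots$kind[h]
      want <- switch(hk, hb_donor = "hb_acceptor", hb_acceptor = "hb_donor",
                     aromatic_ring = "aromatic_ring", NULL)
      if (is.null(want)) next
      anchor <- as.numeric(hotspots[h, c("x", "y", "z")])
      hdir <- as.numeric(hotspots[h, c("dx", "dy", "dz")])
      if (any(is.na(hdir))) next
      for (f in which(feats$kind == want)) {
        fpos <- as.numeric(feats[f, c("x", "y", "z")])
        fdir0 <- as.numeric(feats[f, c("dx", "dy", "dz")])
        ideal_d <- if (hk == "aromatic_ring") model$ar_dist[["ideal"]] else model$hb_dist[["ideal"]]
        target <- anchor + hdir * ideal_d
        # a ring feature has no intrinsic normal sign: enumerate both faces
        # (this also makes the pose set frame-independent, since the sign
        # the plane fit returns is arbitrary)
        fdirs <- if (hk == "aromatic_ring") list(fdir0, -fdir0) else list(fdir0)
        for (fc in seq_along(fdirs)) {
        fdir <- fdirs[[fc]]
        # orient the feature direction against the hotspot direction
        R <- .rotation_between(fdir, -hdir)
        Xr <- sweep(sweep(xyz0, 2, fpos) %*% t(R), 2, target, "+")
        # anchor the spin phase to the pocket centroid so the orientation
        # grid is equivariant under rigid motion of the complex
        perp_of <- function(v) v - sum(v * hdir) * hdir
        v_ref <- perp_of(pocket$centroid - target)
        # probe-side reference: the heavy atom farthest off the spin axis
        # (the centroid can sit almost on the axis, making its azimuth
        # numerically unstable)
        offs <- sweep(Xr[hv, , drop = FALSE], 2, target)
        perp2 <- rowSums(offs^2) - (offs %*% hdir)^2
        v_probe <- perp_of(Xr[hv[which.max(perp2)], ] - target)
        if (sum(v_ref^2) > 1e-8 && sum(v_probe^2) > 1e-8) {
          phase <- atan2(sum(cross3(v_probe, v_ref) * hdir), sum(v_probe * v_ref))
          Xr <- rotate_about_axis(Xr, hdir, target, phase)
        }
        for (o in seq_len(n_orientations)) {
          ang <- 2 * pi * (o - 1) / n_orientations
          X <- rotate_about_axis(Xr, hdir, target, ang)
          hxyz <- X[hv, , drop = FALSE]
          if (max(rowSums(sweep(hxyz, 2, pocket$centroid)^2)) > (pocket_r + 3)^2) next
          if (has_hard_clash(hxyz, el, pocket, clash_ratio)) next
          ph <- pharmacophore_score(probe, X, hotspots, model)
          if (ph$score <= 0) next
          e <- binding_energy(probe, X, pocket, hotspots, model)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            mol = list(probe), pose = list(X),
            pharmacophore_score = ph$score, binding_energy = e,
            matched = list(ph$matched),
            conformer = ci, hotspot = h,
            orientation = o + (fc - 1L) * n_orientations
          )
        }
        }
      }
    }
  }
  if (!length(rows)) {
    warning("no feasible probe placement (no complementary hotspot pairing)")
    return(tibble::tibble(mol = list(), pose = list(),
                          pharmacophore_score = numeric(), binding_energy = numeric(),
                          matched = list(), conformer = integer(),
                          hotspot = integer(), orientation = integer()))
  }
  out <- dplyr::bind_rows(rows)
  # scores are rounded for ranking so that floating-point jitter cannot
  # reorder ties; equal keys keep deterministic enumeration order
  dplyr::arrange(out, dplyr::desc(round(.data$pharmacophore_score, 6)),
                 round(.data$binding_energy, 6))
}

#' Default rigid-body pose refiner
#'
#' Local 6-DOF optimization of the empirical energy with a 2 angstrom
#' centroid trust region; the refined energy never exceeds the starting
#' energy. This is the built-in realization of the pose-refiner contract;
#' [xtb_refiner()] plugs an external program into the same slot.
#'
#' @param mol,xyz pose to refine.
#' @param pocket,hotspots,model interaction field.
#' @param trust_radius maximum centroid displacement (angstroms).
#' @param maxit optimizer iterations.
#' @return list with `xyz` and `energy`.
#' @export
default_refine <- function(mol, xyz, pocket, hotspots, model = default_energy_model(),
                           trust_radius = 2.0, maxit = 200L) {
  hv <- heavy_atoms(mol)
  center <- colMeans(xyz[hv, , drop = FALSE])
  scorer <- make_pose_scorer(mol, xyz, pocket, hotspots, model)
  obj <- function(par) {
    if (sqrt(sum(par[4:6]^2)) > trust_radius) return(1e9)
    scorer(R = rotation_from_vector(par[1:3]), t = par[4:6], center = center)
  }
  e0 <- obj(rep(0, 6))
  if (!is.finite(e0)) stop("non-finite starting energy in refinement")
  opt <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-9))
  if (opt$value < e0) {
    list(xyz = apply_rigid_params(xyz, opt$par, center), energy = opt$value)
  } else {
    list(xyz = xyz, energy = e0)
  }
}

#' Build the default pose-refiner object
#' @return a refiner: list with `name` and `refine(mol, xyz, pocket,
#'   hotspots, model)`.
#' @export
default_refiner <- function() {
  list(name = "rigid-empirical", refine = default_refine)
}

#' External quantum-refiner adapter
#'
#' Plugs an external pose-refinement executable into the refiner contract.
#' The command is invoked as `cmd ligand.sdf pocket.pdb out.sdf`; the pocket
#' file holds the residues within `pocket_radius` angstroms of the probe; the
#' command must write the refined ligand (same atoms, same order) to
#' `out.sdf`. The refined pose is re-scored with the package energy model and
#' is only accepted if it does not worsen the energy, so the contract
#' (topology preserved, energy non-increasing) holds regardless of the
#' external program. Off by default; the internal refiner needs no external
#' software.
#'
#' @param cmd path to the executable.
#' @param pocket_radius residue truncation radius (default 8).
#' @return a refiner object (same contract as [default_refiner()]).
#' @export
xtb_refiner <- function(cmd, pocket_radius = 8.0) {
  force(cmd); force(pocket_radius)
  list(
    name = paste0("external:", basename(cmd)),
    refine = function(mol, xyz, pocket, hotspots, model = default_energy_model()) {
      e0 <- binding_energy(mol, xyz, pocket, hotspots, model)
      td <- tempfile("xtbref"); dir.create(td)
      lig <- file.path(td, "ligand.sdf"); out <- file.path(td, "out.sdf")
      ppdb <- file.path(td, "pocket.pdb")
      m2 <- mol; m2$conformers <- list(xyz)
      writeLines(mol_to_molblock(m2, conformer = 1), lig)
      hv <- heavy_atoms(mol)
      sub <- extract_pocket(pocket$protein, xyz[hv, , drop = FALSE], cutoff = pocket_radius)
      sub_prot <- structure(list(atoms = pocket_atoms(sub),
                                 hetatm = pocket$protein$hetatm[0, ], source = ""),
                            class = "fg_protein")
      write_protein(sub_prot, ppdb)
      status <- system2(cmd, c(lig, ppdb, out), stdout = FALSE, stderr = FALSE)
      if (status != 0 || !file.exists(out)) {
        warning("external refiner failed; keeping input pose")
        return(list(xyz = xyz, energy = e0))
      }
      ref <- parse_molecule(paste(readLines(out), collapse = "\n"), format = "sdf")
      if (n_atoms(ref) != n_atoms(mol) || !length(ref$conformers)) {
        warning("external refiner changed topology; keeping input pose")
        return(list(xyz = xyz, energy = e0))
      }
      x2 <- ref$conformers[[1]]
      e2 <- binding_energy(mol, x2, pocket, hotspots, model)
      if (e2 <= e0 + 1e-6) list(xyz = x2, energy = e2) else list(xyz = xyz, energy = e0)
    }
  )
}

#' Select the best probe poses
#'
#' Ranks placements by `pharmacophore_score - energy_weight * binding_energy`
#' after deduplicating near-identical poses of the same molecule (pairwise
#' heavy-atom RMSD below `dedup_rmsd`; the better-ranked pose survives).
#'
#' @param poses tibble from [enumerate_probe_placements()] (possibly refined).
#' @param k number of poses to keep.
#' @param energy_weight weight of the energy term in the combined rank.
#' @param dedup_rmsd pose deduplication threshold (angstroms).
#' @param per_molecule round-robin across probe molecules so every probe
#'   keeps its best placements even when one probe dominates the ranking.
#' @return tibble of at most `k` rows, best first within molecule rank.
#' @export
select_probes <- function(poses, k = 5L, energy_weight = 0.1, dedup_rmsd = 1.0,
                          per_molecule = FALSE) {
  stopifnot(k >= 1)
  if (!nrow(poses)) stop("empty placement list")
  poses$combined <- poses$pharmacophore_score - energy_weight * poses$binding_energy
  poses$smiles <- vapply(poses$mol, canonical_smiles, character(1))
  poses <- dplyr::arrange(poses, dplyr::desc(.data$combined))
  keep <- logical(nrow(poses))
  for (i in seq_len(nrow(poses))) {
    dup <- FALSE
    hi <- heavy_atoms(poses$mol[[i]])
    for (j in which(keep)) {
      if (!identical(poses$smiles[j], poses$smiles[i])) next
      if (nrow(poses$pose[[j]]) != nrow(poses$pose[[i]])) next
      if (rmsd(poses$pose[[i]][hi, , drop = FALSE],
               poses$pose[[j]][hi, , drop = FALSE]) < dedup_rmsd) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  out <- poses[keep, , drop = FALSE]
  if (k > nrow(out)) {
    warning("requested ", k, " probes, only ", nrow(out), " available after dedup")
  }
  if (per_molecule && length(unique(out$smiles)) > 1) {
    # interleave: best of each molecule, then second-best of each, ...
    rank_within <- stats::ave(seq_len(nrow(out)), out$smiles, FUN = seq_along)
    out <- out[order(rank_within, -out$combined), , drop = FALSE]
  }
  utils::head(out, k)
}
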