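# Binding-site definition and typed hotspot detection.

#' Extract the binding pocket around a reference ligand
#'
#' The pocket is every protein residue having at least one heavy atom within
#' `cutoff` angstroms of any reference-ligand heavy atom — the common
#' contact-shell convention. De novo site detection is deliberately not
#' implemented; a reference ligand is required.
#'
#' @param protein an `fg_protein` from [read_protein()].
#' @param reference the reference ligand: a molecule carrying one conformer,
#'   or a plain `n x 3` matrix of heavy-atom coordinates.
#' @param cutoff contact distance in angstroms (default 5).
#' @return an `fg_pocket`: list with `protein`, `residues` (character keys),
#'   `atom_idx` (row indices into `protein$atoms`), `bbox` (2 x 3 matrix),
#'   `centroid`, and `reference` (the ligand, if a molecule was given).
#' @export
extract_pocket <- function(protein, reference, cutoff = 5.0) {
  stopifnot(inherits(protein, "fg_protein"), cutoff > 0)
  if (is_molecule(reference)) {
    stopifnot(length(reference$conformers) >= 1)
    ref_xyz <- reference$conformers[[1]][heavy_atoms(reference), , drop = FALSE]
    ref_mol <- reference
  } else {
    ref_xyz <- as.matrix(reference)
    ref_mol <- NULL
  }
  stopifnot(nrow(ref_xyz) >= 1)
  pxyz <- protein_xyz(protein)
  heavy <- protein$atoms$element != "H"
  d2 <- outer(rowSums(pxyz^2), rowSums(ref_xyz^2), "+") - 2 * pxyz %*% t(ref_xyz)
  near <- apply(d2, 1, min) <= cutoff^2 & heavy
  if (!any(near)) stop("reference outside protein: no atom within ", cutoff, " A")
  residues <- sort(unique(protein$atoms$reskey[near]))
  atom_idx <- which(protein$atoms$reskey %in% residues)
  xyz <- pxyz[atom_idx, , drop = FALSE]
  structure(
    list(
      protein = protein,
      residues = residues,
      atom_idx = atom_idx,
      bbox = rbind(apply(xyz, 2, min), apply(xyz, 2, max)),
      centroid = colMeans(xyz),
      reference = ref_mol
    ),
    class = "fg_pocket"
  )
}

#' @export
print.fg_pocket <- function(x, ...) {
  cat(sprintf("<pocket: %d residues, %d atoms>\n", length(x$residues), length(x$atom_idx)))
  invisible(x)
}

pocket_atoms <- function(pocket) {
  pocket$protein$atoms[pocket$atom_idx, , drop = FALSE]
}

#' Load a hotspot typing table
#'
#' @param path YAML file in the layout of
#'   `system.file("extdata", "hotspot_rules.yaml", package = "fraggrow")`.
#' @return a named list (donors / acceptors / aromatic_rings / hydrophobic).
#' @export
load_hotspot_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hotspot_rules.yaml", package = "fraggrow")
  }
  yaml::read_yaml(path)
}

# Heavy-atom neighbors within covalent range, per atom, on a coordinate set.
.covalent_neighbors <- function(atoms, xyz) {
  n <- nrow(atoms)
  D <- as.matrix(stats::dist(xyz))
  diag(D) <- Inf
  cut <- outer(covalent_radius(atoms$element), covalent_radius(atoms$element), "+") * 1.3
  lapply(seq_len(n), function(i) which(D[i, ] <= cut[i, ]))
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) return(c(0, 0, 0))
  v / nv
}

#' Detect typed hotspots in a pocket
#'
#' Hydrogen-bond donors are N/O/S atoms typed by the rules table; the
#' direction follows the attached hydrogen when hydrogens are present in the
#' structure and otherwise points away from the bonded heavy atoms.
#' Acceptors point along the lone-pair bisector (away from bonded heavy
#' atoms). Aromatic hotspots sit at the ring centroid with the ring normal
#' as direction. Hydrophobic hotspots are centroids of clusters of mutually
#' close apolar carbons (complete linkage) and carry no direction.
#'
#' @param pocket an `fg_pocket`.
#' @param rules typing table from [load_hotspot_rules()].
#' @param include_hydrophobic detect hydrophobic patch hotspots as well.
#' @return tibble with `kind`, `reskey`, `label`, anchor `x`,`y`,`z` and unit
#'   direction `dx`,`dy`,`dz` (NA for hydrophobic), ordered deterministically
#'   by residue key then kind then label.
#' @export
detect_hotspots <- function(pocket, rules = load_hotspot_rules(),
                            include_hydrophobic = TRUE) {
  stopifnot(inherits(pocket, "fg_pocket"))
  atoms <- pocket_atoms(pocket)
  if (!nrow(atoms)) stop("empty pocket")
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  nbrs <- .covalent_neighbors(atoms, xyz)
  is_h <- atoms$element == "H"
  out <- list()
  emit <- function(kind, reskey, label, anchor, dir) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      kind = kind, reskey = reskey, label = label,
      x = anchor[1], y = anchor[2], z = anchor[3],
      dx = dir[1], dy = dir[2], dz = dir[3]
    )
  }

  typed_atoms <- function(table) {
    hits <- integer()
    for (i in seq_len(nrow(atoms))) {
      nm <- atoms$atom_name[i]
      if (nm %in% (table[["backbone"]] %||% character()) && atoms$resname[i] != "PRO") {
        hits <- c(hits, i); next
      }
      res_tab <- table[[atoms$resname[i]]]
      if (!is.null(res_tab) && nm %in% res_tab) hits <- c(hits, i)
    }
    hits
  }

  # donors
  for (i in typed_atoms(rules$donors)) {
    hs <- nbrs[[i]][is_h[nbrs[[i]]]]
    if (length(hs)) {
      for (h in hs) {
        emit("hb_donor", atoms$reskey[i], paste0(atoms$atom_name[i], "-", atoms$atom_name[h]),
             xyz[i, ], unit(xyz[h, ] - xyz[i, ]))
      }
    } else {
      heavy_nb <- nbrs[[i]][!is_h[nbrs[[i]]]]
      if (!length(heavy_nb)) next
      emit("hb_donor", atoms$reskey[i], atoms$atom_name[i],
           xyz[i, ], unit(xyz[i, ] - colMeans(xyz[heavy_nb, , drop = FALSE])))
    }
  }

  # acceptors
  for (i in typed_atoms(rules$acceptors)) {
    heavy_nb <- nbrs[[i]][!is_h[nbrs[[i]]]]
    if (!length(heavy_nb)) next
    emit("hb_acceptor", atoms$reskey[i], atoms$atom_name[i],
         xyz[i, ], unit(xyz[i, ] - colMeans(xyz[heavy_nb, , drop = FALSE])))
  }

  # aromatic rings
  for (res in split(seq_len(nrow(atoms)), atoms$reskey)) {
    resname <- atoms$resname[res[1]]
    ring_names <- rules$aromatic_rings[[resname]]
    if (is.null(ring_names)) next
    idx <- res[match(ring_names, atoms$atom_name[res])]
    if (any(is.na(idx))) next
    centroid <- colMeans(xyz[idx, , drop = FALSE])
    sv <- svd(sweep(xyz[idx, , drop = FALSE], 2, centroid))
    normal <- unit(sv$v[, 3])
    # orient the stacking face toward the pocket interior (the plane-fit
    # sign is otherwise arbitrary and frame-dependent)
    if (sum(normal * (pocket$centroid - centroid)) < 0) normal <- -normal
    emit("aromatic_ring", atoms$reskey[res[1]], "ring", centroid, normal)
  }

  # hydrophobic patches
  if (include_hydrophobic) {
    hp <- rules$hydrophobic %||% list(min_atoms = 3, cluster_distance = 5.0)
    apolar <- which(atoms$element == "C" & vapply(seq_len(nrow(atoms)), function(i) {
      nb <- nbrs[[i]]
      !any(atoms$element[nb] %in% c("N", "O", "S"))
    }, logical(1)))
    if (length(apolar) >= hp$min_atoms) {
      hc <- stats::hclust(stats::dist(xyz[apolar, , drop = FALSE]), method = "complete")
      grp <- stats::cutree(hc, h = hp$cluster_distance)
      for (g in sort(unique(grp))) {
        members <- apolar[grp == g]
        if (length(members) < hp$min_atoms) next
        centroid <- colMeans(xyz[members, , drop = FALSE])
        key <- sort(unique(atoms$reskey[members]))[1]
        emit("hydrophobic_patch", key, paste0("patch", g), centroid, c(NA_real_, NA_real_, NA_real_))
      }
    }
  }

  if (!length(out)) {
    warning("no hotspots detected in pocket")
    return(tibble::tibble(kind = character(), reskey = character(), label = character(),
                          x = numeric(), y = numeric(), z = numeric(),
                          dx = numeric(), dy = numeric(), dz = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$reskey, .data$kind, .data$label)
}

#' Dump hotspots as a pseudo-atom PDB file for visual inspection
#'
#' One HETATM per hotspot; element encodes the kind (N = donor, O = acceptor,
#' C = aromatic ring centroid, S = hydrophobic patch).
#'
#' @param hotspots tibble from [detect_hotspots()].
#' @param path output PDB path.
#' @export
write_hotspots_pdb <- function(hotspots, path) {
  el <- c(hb_donor = "N", hb_acceptor = "O", aromatic_ring = "C",
          hydrophobic_patch = "S")[hotspots$kind]
  n <- nrow(hotspots)
  bio3d::write.pdb(
    file = path, type = rep("HETATM", n), eleno = seq_len(n),
    elety = el, resid = rep("HOT", n), chain = rep("Z", n), resno = seq_len(n),
    xyz = as.vector(t(as.matrix(hotspots[, c("x", "y", "z")]))),
    o = rep(1, n), b = rep(0, n), elesy = el
  )
  invisible(path)
}

hotspot_xyz <- function(hotspots) as.matrix(hotspots[, c("x", "y", "z")])
hotspot_dir <- function(hotspots) as.matrix(hotspots[, c("dx", "dy", "dz")])
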