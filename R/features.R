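# Ligand-side pharmacophore features, typed from the molecular graph and
# positioned by a conformer. The typing mirrors the pocket-side hotspot
# table: donors are N/O/S bearing hydrogen; acceptors are carbonyl, hydroxyl,
# ether and anionic oxygens plus pyridine-type and amine nitrogens (amide,
# pyrrole-type and positively charged nitrogens are excluded); aromatic
# features are ring centroids with normals; apolar carbons carry the
# hydrophobic term.

ligand_acceptor_atoms <- function(mol) {
  out <- integer()
  for (a in heavy_atoms(mol)) {
    el <- mol$atoms$element[a]
    chg <- mol$atoms$charge[a]
    if (chg > 0) next
    if (el == "O") {
      if (mol$atoms$aromatic[a]) next  # furan-type O: poor acceptor
      out <- c(out, a)
    } else if (el == "N") {
      nh <- n_hydrogens(mol, a)
      nb <- atom_neighbors(mol, a)
      heavy_nb <- nb[mol$atoms$element[nb] != "H"]
      if (mol$atoms$aromatic[a]) {
        # pyridine-type: aromatic N, two ring neighbors, no H
        if (nh == 0 && length(heavy_nb) == 2) out <- c(out, a)
      } else {
        # exclude amide N (bonded to a carbonyl carbon) and aniline-type N
        # (lone pair delocalized into an aromatic ring)
        amide <- any(vapply(heavy_nb, function(c0) {
          if (mol$atoms$element[c0] != "C") return(FALSE)
          cb <- mol$bonds
          k <- which((cb$i == c0 | cb$j == c0) & cb$order == 2L)
          any(mol$atoms$element[setdiff(c(cb$i[k], cb$j[k]), c0)] == "O")
        }, logical(1)))
        aniline <- any(mol$atoms$aromatic[heavy_nb])
        if (!amide && !aniline && length(heavy_nb) + nh <= 3) out <- c(out, a)
      }
    }
  }
  sort(unique(out))
}

ligand_donor_atoms <- function(mol) {
  hits <- integer()
  for (a in heavy_atoms(mol)) {
    if (mol$atoms$element[a] %in% c("N", "O", "S") && n_hydrogens(mol, a) >= 1) {
      hits <- c(hits, a)
    }
  }
  hits
}

ligand_apolar_atoms <- function(mol) {
  out <- integer()
  for (a in heavy_atoms(mol)) {
    if (mol$atoms$element[a] != "C") next
    nb <- atom_neighbors(mol, a)
    if (!any(mol$atoms$element[nb] %in% c("N", "O", "S"))) out <- c(out, a)
  }
  out
}

aromatic_ring_sets <- function(mol) {
  rings <- smallest_rings(mol)
  keep <- list()
  for (r in rings) {
    if (all(mol$atoms$aromatic[r])) keep[[length(keep) + 1L]] <- r
  }
  keep
}

# Coordinate-independent feature typing of a molecule: which atoms are
# donors (with their hydrogens), acceptors (with their heavy neighbors,
# for lone-pair directions), aromatic rings and apolar carbons. Computed
# once per molecule; positions follow from any pose by indexing.
feature_typing <- function(mol) {
  donors <- ligand_donor_atoms(mol)
  don_pairs <- list()
  for (a in donors) {
    hs <- atom_neighbors(mol, a)
    hs <- hs[mol$atoms$element[hs] == "H"]
    for (h in hs) don_pairs[[length(don_pairs) + 1L]] <- c(a, h)
  }
  acceptors <- ligand_acceptor_atoms(mol)
  acc_nb <- lapply(acceptors, function(a) {
    nb <- atom_neighbors(mol, a)
    nb[mol$atoms$element[nb] != "H"]
  })
  list(
    donor = if (length(don_pairs)) do.call(rbind, don_pairs) else matrix(0L, 0, 2),
    acceptor = acceptors, acceptor_nb = acc_nb,
    rings = aromatic_ring_sets(mol),
    apolar = ligand_apolar_atoms(mol)
  )
}

# Feature positions and directions for a pose, from a typing record.
# Returns list of matrices: anchors `x` and unit directions `d` per kind.
position_features <- function(typing, xyz) {
  nd <- nrow(typing$donor)
  don_x <- xyz[typing$donor[, 1], , drop = FALSE]
  don_d <- if (nd) {
    v <- xyz[typing$donor[, 2], , drop = FALSE] - don_x
    v / sqrt(rowSums(v^2))
  } else matrix(0, 0, 3)
  na <- length(typing$acceptor)
  acc_x <- xyz[typing$acceptor, , drop = FALSE]
  acc_d <- matrix(0, na, 3)
  for (q in seq_len(na)) {
    nb <- typing$acceptor_nb[[q]]
    if (length(nb)) acc_d[q, ] <- unit(acc_x[q, ] - colMeans(xyz[nb, , drop = FALSE]))
  }
  nr <- length(typing$rings)
  ring_x <- matrix(0, nr, 3); ring_d <- matrix(0, nr, 3)
  for (q in seq_len(nr)) {
    M <- xyz[typing$rings[[q]], , drop = FALSE]
    ctr <- colMeans(M)
    ring_x[q, ] <- ctr
    ring_d[q, ] <- unit(svd(sweep(M, 2, ctr))$v[, 3])
  }
  list(don_x = don_x, don_d = don_d, acc_x = acc_x, acc_d = acc_d,
       ring_x = ring_x, ring_d = ring_d,
       apolar_x = xyz[typing$apolar, , drop = FALSE])
}

#' Pharmacophore features of a posed ligand
#'
#' @param mol a molecule.
#' @param xyz full-atom coordinate matrix (defaults to the first conformer).
#' @return tibble with `kind` (`hb_donor`, `hb_acceptor`, `aromatic_ring`,
#'   `apolar`), `atom` (anchor atom index, NA for rings), anchor `x`,`y`,`z`
#'   and unit direction `dx`,`dy`,`dz` (donor: heavy atom toward H; acceptor:
#'   lone-pair bisector; ring: normal; apolar: NA).
#' @export
ligand_features <- function(mol, xyz = NULL) {
  if (is.null(xyz)) {
    stopifnot(length(mol$conformers) >= 1)
    xyz <- mol$conformers[[1]]
  }
  ty <- feature_typing(mol)
  pf <- position_features(ty, xyz)
  nd <- nrow(ty$donor); na <- length(ty$acceptor)
  nr <- length(ty$rings); np <- length(ty$apolar)
  anchors <- rbind(pf$don_x, pf$acc_x, pf$ring_x, pf$apolar_x)
  dirs <- rbind(pf$don_d, pf$acc_d, pf$ring_d,
                matrix(NA_real_, np, 3))
  tibble::tibble(
    kind = c(rep("hb_donor", nd), rep("hb_acceptor", na),
             rep("aromatic_ring", nr), rep("apolar", np)),
    atom = c(if (nd) ty$donor[, 1] else integer(), ty$acceptor,
             rep(NA_integer_, nr), ty$apolar),
    x = anchors[, 1], y = anchors[, 2], z = anchors[, 3],
    dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3]
  )
}
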