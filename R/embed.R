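# Deterministic distance-restraint conformer embedder.
#
# Coordinates are generated by minimizing a molecular stress function built
# from ideal bond lengths (covalent radii), 1-3 distances (hybridization or
# ring interior angles), regular-polygon restraints for aromatic rings,
# planarity (improper) terms at sp2 centers, and soft lower bounds between
# nonbonded atoms. Starting points come from classical MDS of the graph
# distance matrix plus seeded jitter, so the whole procedure is bitwise
# reproducible from the R random seed — a property the pipeline relies on.

.BOND_SCALE <- c(`1` = 1.00, `2` = 0.87, `3` = 0.78)
.AROMATIC_SCALE <- 0.92

# Unique smallest rings: list of atom-index vectors (ordered around the ring).
smallest_rings <- function(mol) {
  b <- mol$bonds
  ring_bonds <- which(b$in_ring)
  if (!length(ring_bonds)) return(list())
  g <- igraph::graph_from_edgelist(as.matrix(b[, c("i", "j")]), directed = FALSE)
  if (igraph::vcount(g) < n_atoms(mol)) {
    g <- igraph::add_vertices(g, n_atoms(mol) - igraph::vcount(g))
  }
  rings <- list()
  seen <- character()
  for (k in ring_bonds) {
    eid <- igraph::get_edge_ids(g, c(b$i[k], b$j[k]))
    g2 <- igraph::delete_edges(g, eid)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = b$i[k], to = b$j[k])$vpath[[1]])
    if (!length(sp)) next
    cyc <- as.integer(sp)
    key <- paste(sort(cyc), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- cyc
    }
  }
  rings
}

# sp-hybridization guess per atom: 1 = sp, 2 = sp2, 3 = sp3.
hybridization <- function(mol) {
  n <- n_atoms(mol)
  hyb <- rep(3L, n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    if (b$order[k] == 3L) hyb[c(b$i[k], b$j[k])] <- 1L
    else if (b$order[k] == 2L || b$aromatic[k]) {
      hyb[b$i[k]] <- pmin(hyb[b$i[k]], 2L)
      hyb[b$j[k]] <- pmin(hyb[b$j[k]], 2L)
    }
  }
  # amide/aniline-type N: trivalent N bonded to an sp2 carbon is planarized
  for (a in which(mol$atoms$element == "N" & hyb == 3L)) {
    nb <- atom_neighbors(mol, a)
    if (any(hyb[nb] == 2L & mol$atoms$element[nb] == "C")) hyb[a] <- 2L
  }
  hyb
}

ideal_bond_length <- function(mol, k) {
  b <- mol$bonds[k, ]
  base <- covalent_radius(mol$atoms$element[b$i]) + covalent_radius(mol$atoms$element[b$j])
  if (b$aromatic) base * .AROMATIC_SCALE else base * .BOND_SCALE[[as.character(b$order)]]
}

# Build the restraint set once per molecule.
embed_restraints <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  hyb <- hybridization(mol)
  rings <- smallest_rings(mol)

  pair_i <- integer(); pair_j <- integer(); target <- numeric(); weight <- numeric()
  add_pair <- function(i, j, t, w) {
    pair_i <<- c(pair_i, min(i, j)); pair_j <<- c(pair_j, max(i, j))
    target <<- c(target, t); weight <<- c(weight, w)
  }

  blen <- numeric(nrow(b))
  for (k in seq_len(nrow(b))) {
    blen[k] <- ideal_bond_length(mol, k)
    add_pair(b$i[k], b$j[k], blen[k], 10)
  }

  # ring membership of bonds for interior-angle decisions
  bond_key <- paste(b$i, b$j)
  bond_len_of <- function(i, j) blen[match(paste(min(i, j), max(i, j)), bond_key)]
  ring_of_pair <- function(a, c, bnd) {
    for (r in rings) {
      m <- length(r)
      for (q in seq_len(m)) {
        trip <- c(r[(q - 2) %% m + 1], r[(q - 1) %% m + 1], r[q %% m + 1])
        if (trip[2] == c && ((trip[1] == a && trip[3] == bnd) || (trip[1] == bnd && trip[3] == a))) {
          return(m)
        }
      }
    }
    NA_integer_
  }

  # 1-3 restraints from angles
  for (c0 in seq_len(n)) {
    nb <- atom_neighbors(mol, c0)
    if (length(nb) < 2) next
    for (p in seq_len(length(nb) - 1)) {
      for (q in (p + 1):length(nb)) {
        a <- nb[p]; d <- nb[q]
        rs <- if (mol$atoms$in_ring[c0]) ring_of_pair(a, c0, d) else NA_integer_
        theta <- if (!is.na(rs)) pi * (rs - 2) / rs
        else c(pi, 2 * pi / 3, acos(-1 / 3))[hyb[c0]]
        la <- bond_len_of(a, c0); ld <- bond_len_of(d, c0)
        t13 <- sqrt(la^2 + ld^2 - 2 * la * ld * cos(theta))
        add_pair(a, d, t13, 4)
      }
    }
  }

  # aromatic rings: full regular-polygon distance set
  for (r in rings) {
    m <- length(r)
    ring_bond_arom <- TRUE
    for (q in seq_len(m)) {
      i <- r[q]; j <- r[q %% m + 1]
      k <- match(paste(min(i, j), max(i, j)), bond_key)
      if (is.na(k) || !b$aromatic[k]) { ring_bond_arom <- FALSE; break }
    }
    if (!ring_bond_arom || m < 4) next
    side <- mean(vapply(seq_len(m), function(q) {
      i <- r[q]; j <- r[q %% m + 1]
      blen[match(paste(min(i, j), max(i, j)), bond_key)]
    }, numeric(1)))
    circ <- side / (2 * sin(pi / m))
    for (p in seq_len(m - 1)) {
      for (q in (p + 1):m) {
        sep <- min(abs(p - q), m - abs(p - q))
        if (sep <= 1) next
        t <- 2 * circ * sin(pi * sep / m)
        add_pair(r[p], r[q], t, 4)
      }
    }
  }

  # improper (planarity) centers: sp2 atoms with exactly 3 neighbors
  imp <- list()
  for (c0 in which(hyb == 2L)) {
    nb <- atom_neighbors(mol, c0)
    if (length(nb) == 3) imp[[length(imp) + 1L]] <- c(c0, nb)
  }

  # nonbonded lower bounds for graph distance >= 3 pairs not already restrained
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(b)) g <- igraph::add_edges(g, t(as.matrix(b[, c("i", "j")])))
  gd <- igraph::distances(g)
  have <- paste(pair_i, pair_j)
  nb_i <- integer(); nb_j <- integer(); lb <- numeric()
  vr <- vdw_radius(mol$atoms$element)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (is.finite(gd[i, j]) && gd[i, j] < 3) next
      if (paste(i, j) %in% have) next
      nb_i <- c(nb_i, i); nb_j <- c(nb_j, j)
      lb <- c(lb, 0.7 * (vr[i] + vr[j]))
    }
  }

  list(pair_i = pair_i, pair_j = pair_j, target = target, weight = weight,
       imp = imp, nb_i = nb_i, nb_j = nb_j, lb = lb, n = n)
}

embed_stress <- function(x, rs, w_imp = 20) {
  X <- matrix(x, rs$n, 3)
  D <- X[rs$pair_i, , drop = FALSE] - X[rs$pair_j, , drop = FALSE]
  d <- sqrt(rowSums(D^2))
  e <- sum(rs$weight * (d - rs$target)^2)
  if (length(rs$nb_i)) {
    Dn <- X[rs$nb_i, , drop = FALSE] - X[rs$nb_j, , drop = FALSE]
    dn <- sqrt(rowSums(Dn^2))
    viol <- pmax(0, rs$lb - dn)
    e <- e + 2 * sum(viol^2)
  }
  for (t in rs$imp) {
    v1 <- X[t[2], ] - X[t[1], ]; v2 <- X[t[3], ] - X[t[1], ]; v3 <- X[t[4], ] - X[t[1], ]
    vol <- det(cbind(v1, v2, v3))
    e <- e + w_imp * vol^2
  }
  e
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

scatter_add <- function(G, idx, M) {
  S <- rowsum(M, group = idx)
  rows <- as.integer(rownames(S))
  G[rows, ] <- G[rows, ] + S
  G
}

embed_gradient <- function(x, rs, w_imp = 20) {
  X <- matrix(x, rs$n, 3)
  G <- matrix(0, rs$n, 3)
  D <- X[rs$pair_i, , drop = FALSE] - X[rs$pair_j, , drop = FALSE]
  d <- pmax(sqrt(rowSums(D^2)), 1e-9)
  GP <- D * (2 * rs$weight * (d - rs$target) / d)
  G <- scatter_add(G, rs$pair_i, GP)
  G <- scatter_add(G, rs$pair_j, -GP)
  if (length(rs$nb_i)) {
    Dn <- X[rs$nb_i, , drop = FALSE] - X[rs$nb_j, , drop = FALSE]
    dn <- pmax(sqrt(rowSums(Dn^2)), 1e-9)
    viol <- pmax(0, rs$lb - dn)
    GN <- Dn * (-4 * viol / dn)
    G <- scatter_add(G, rs$nb_i, GN)
    G <- scatter_add(G, rs$nb_j, -GN)
  }
  for (t in rs$imp) {
    v1 <- X[t[2], ] - X[t[1], ]; v2 <- X[t[3], ] - X[t[1], ]; v3 <- X[t[4], ] - X[t[1], ]
    vol <- det(cbind(v1, v2, v3))
    g1 <- cross3(v2, v3); g2 <- cross3(v3, v1); g3 <- cross3(v1, v2)
    f <- 2 * w_imp * vol
    G[t[2], ] <- G[t[2], ] + f * g1
    G[t[3], ] <- G[t[3], ] + f * g2
    G[t[4], ] <- G[t[4], ] + f * g3
    G[t[1], ] <- G[t[1], ] - f * (g1 + g2 + g3)
  }
  as.vector(G)
}

# One embedding attempt from a seeded start. Returns list(xyz, stress).
embed_once <- function(mol, rs, jitter_sd = 0.4) {
  n <- rs$n
  # classical MDS on graph distances as a well-shaped start
  b <- mol$bonds
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(b)) g <- igraph::add_edges(g, t(as.matrix(b[, c("i", "j")])))
  gd <- igraph::distances(g)
  gd[!is.finite(gd)] <- max(gd[is.finite(gd)]) + 2
  X0 <- tryCatch({
    fit <- stats::cmdscale(gd * 1.5, k = 3)
    if (ncol(fit) < 3) cbind(fit, matrix(0, n, 3 - ncol(fit))) else fit
  }, error = function(e) matrix(0, n, 3))
  X0 <- X0 + matrix(stats::rnorm(n * 3, sd = jitter_sd), n, 3)
  opt <- stats::optim(as.vector(X0), fn = embed_stress, gr = embed_gradient, rs = rs,
                      method = "BFGS", control = list(maxit = 500, reltol = 1e-10))
  list(xyz = matrix(opt$par, n, 3), stress = opt$value)
}

#' Generate seeded 3D conformers
#'
#' Embeds the molecular graph into 3D by deterministic multi-start stress
#' minimization (see package vignette for the restraint model). Conformers
#' are deduplicated at 0.5 angstrom heavy-atom RMSD after optimal
#' superposition and returned best-stress first.
#'
#' @param mol a molecule.
#' @param n maximum number of conformers.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @param dedup_rmsd RMSD threshold (angstroms) below which two conformers
#'   count as duplicates.
#' @return list of `n_atoms x 3` coordinate matrices.
#' @export
generate_conformers <- function(mol, n = 20, seed = 1L, dedup_rmsd = 0.5) {
  stopifnot(n >= 1)
  rs <- embed_restraints(mol)
  hv <- heavy_atoms(mol)
  out <- list()
  stresses <- numeric()
  attempts <- list()
  withr::with_seed(seed, {
    n_try <- n + 4L
    for (k in seq_len(n_try)) {
      jit <- if (k == 1) 0.25 else 0.25 + 1.25 * (k - 1) / n_try
      attempts[[k]] <- embed_once(mol, rs, jitter_sd = jit)
    }
  })
  ord <- order(vapply(attempts, `[[`, numeric(1), "stress"))
  base_stress <- attempts[[ord[1]]]$stress
  for (k in ord) {
    cand <- attempts[[k]]
    if (cand$stress > max(4 * base_stress, base_stress + 5)) next  # poorly converged
    A <- cand$xyz[hv, , drop = FALSE]
    dup <- FALSE
    for (p in out) {
      if (superposed_rmsd(A, p[hv, , drop = FALSE]) < dedup_rmsd) { dup <- TRUE; break }
    }
    if (!dup) {
      out[[length(out) + 1L]] <- cand$xyz
      stresses <- c(stresses, cand$stress)
    }
    if (length(out) >= n) break
  }
  if (!length(out)) stop("conformer embedding failed for ", canonical_smiles(mol))
  out
}

# Embed a single best conformer and attach it to the molecule.
embed_molecule <- function(mol, seed = 1L) {
  mol$conformers <- generate_conformers(mol, n = 1, seed = seed)
  mol
}
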