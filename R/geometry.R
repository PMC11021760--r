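# Rigid-body geometry: Kabsch superposition, 6-DOF transforms, and
# symmetry-aware RMSD over molecular graph automorphisms.

#' Optimal rigid superposition (Kabsch)
#'
#' Returns the rotation `R` and translation `t` minimizing
#' `|| (P %*% R + t) - Q ||` in the least-squares sense. `R` is proper
#' (determinant +1); reflections are never returned.
#'
#' @param P,Q `n x 3` matrices of paired coordinates (`n >= 3`).
#' @return list with `R` (3x3), `t` (length 3), and `rmsd` after fit.
#' @export
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  R <- t(R)  # so that P %*% R aligns onto Q
  t_vec <- cq - as.vector(cp %*% R)
  fitted <- sweep(P %*% R, 2, t_vec, "+")
  list(R = R, t = t_vec, rmsd = rmsd(fitted, Q))
}

apply_rigid <- function(xyz, R, t) {
  sweep(xyz %*% R, 2, t, "+")
}

#' Root-mean-square deviation between two conformations
#'
#' Plain per-index RMSD with no superposition and no symmetry handling.
#'
#' @param A,B `n x 3` coordinate matrices with identical atom ordering.
#' @return RMSD in angstroms.
#' @export
rmsd <- function(A, B) {
  sqrt(mean(rowSums((A - B)^2)))
}

# RMSD after optimal superposition (used for conformer deduplication).
superposed_rmsd <- function(A, B) {
  if (nrow(A) < 3) {
    return(rmsd(sweep(A, 2, colMeans(A)), sweep(B, 2, colMeans(B))))
  }
  k <- kabsch(A, B)
  k$rmsd
}

# Rotation matrix from an axis-angle-style parameter vector (rx, ry, rz):
# rotation by |r| radians about the axis r. Identity at r = 0.
rotation_from_vector <- function(r) {
  theta <- sqrt(sum(r^2))
  if (theta < 1e-12) return(diag(3))
  k <- r / theta
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Apply a 6-parameter rigid move (3 rotation, 3 translation) about a center.
apply_rigid_params <- function(xyz, par, center) {
  R <- rotation_from_vector(par[1:3])
  sweep(sweep(sweep(xyz, 2, center) %*% t(R), 2, center, "+"), 2, par[4:6], "+")
}

# Rotation about an arbitrary unit axis through a point, by angle (radians).
rotate_about_axis <- function(xyz, axis, point, angle) {
  R <- rotation_from_vector(axis / sqrt(sum(axis^2)) * angle)
  sweep(sweep(xyz, 2, point) %*% t(R), 2, point, "+")
}

# ---------------------------------------------------------------------------
# Graph automorphisms (heavy atoms, element/charge/aromatic/H-count colored,
# bond orders respected via edge subdivision)

heavy_automorphisms <- function(mol, max_group = 20000L) {
  g <- heavy_graph(mol)
  nv <- igraph::vcount(g)
  if (nv == 0) return(list())
  el <- igraph::as_edgelist(g, names = FALSE)
  ne <- nrow(el)
  # subdivide each edge with a vertex colored by bond order so that BLISS
  # (vertex colors only) respects edge colors
  g2 <- igraph::make_empty_graph(nv + ne, directed = FALSE)
  if (ne) {
    edges <- rbind(cbind(el[, 1], nv + seq_len(ne)),
                   cbind(el[, 2], nv + seq_len(ne)))
    g2 <- igraph::add_edges(g2, t(edges))
  }
  vlab <- igraph::V(g)$color_label
  vcol <- match(vlab, unique(vlab))
  ecol <- if (ne) max(vcol) + igraph::E(g)$order else integer(0)
  colors <- as.integer(c(vcol, ecol))
  gens <- igraph::automorphism_group(g2, colors = colors)
  gens <- lapply(gens, function(p) as.integer(p)[seq_len(nv)])
  # closure of the generator set (BFS)
  id <- seq_len(nv)
  seen <- new.env(parent = emptyenv())
  key <- function(p) paste(p, collapse = ",")
  assign(key(id), TRUE, envir = seen)
  group <- list(id)
  queue <- list(id)
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (gp in gens) {
      nxt <- cur[gp]
      k <- key(nxt)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        group[[length(group) + 1L]] <- nxt
        queue[[length(queue) + 1L]] <- nxt
        if (length(group) >= max_group) return(group)
      }
    }
  }
  group
}

# Orbits of heavy atoms under the automorphism group; returns an integer
# vector mapping each heavy atom (position in heavy_atoms(mol)) to an orbit id.
heavy_orbits <- function(mol) {
  auts <- heavy_automorphisms(mol)
  nv <- length(heavy_atoms(mol))
  orbit <- seq_len(nv)
  for (p in auts) orbit <- pmin(orbit, orbit[p])
  # iterate to fixed point (cheap for small groups)
  repeat {
    nxt <- orbit
    for (p in auts) nxt <- pmin(nxt, nxt[p])
    if (identical(nxt, orbit)) break
    orbit <- nxt
  }
  match(orbit, unique(orbit))
}

#' Symmetry-aware RMSD between two poses of one molecule
#'
#' Minimum heavy-atom RMSD over the automorphisms of the molecular graph,
#' computed without re-superposition: both poses are compared in the frame
#' they are given in (the pocket frame, for the pose-reproduction benchmark).
#' Automorphisms make e.g. a benzene ring rotated by 60 degrees in place
#' equivalent to the original.
#'
#' @param mol the molecule both poses belong to.
#' @param a,b full-atom `n x 3` coordinate matrices.
#' @return RMSD in angstroms.
#' @export
symmetry_rmsd <- function(mol, a, b) {
  hv <- heavy_atoms(mol)
  A <- a[hv, , drop = FALSE]
  B <- b[hv, , drop = FALSE]
  auts <- heavy_automorphisms(mol)
  best <- Inf
  for (p in auts) {
    # automorphism p maps heavy atom v onto p[v]: compare A[v,] with B[p[v],]
    val <- rmsd(A, B[p, , drop = FALSE])
    if (val < best) best <- val
  }
  best
}
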