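# Geometry engine of the growth loop: alignment to the parent pose,
# rigid-body docking, and shape similarity.

#' Align a conformer onto its parent pose
#'
#' Least-squares rigid superposition (Kabsch) of the conformer's inherited
#' atoms onto the corresponding atoms of the parent pose. The map comes from
#' growth lineage provenance; at least 3 pairs are required for a determined
#' fit (with 3 collinear atoms the rotation about the common axis is
#' whatever the SVD returns — deterministic, minimal-rotation by
#' construction).
#'
#' @param conf_xyz full-atom conformer coordinates of the child molecule.
#' @param parent_xyz full-atom pose of the parent.
#' @param map two-column integer matrix: child atom index, parent atom index.
#' @return list with `xyz` (transformed child coordinates) and `rmsd` (the
#'   residual over mapped atoms, angstroms).
#' @export
align_to_parent <- function(conf_xyz, parent_xyz, map) {
  map <- as.matrix(map)
  if (nrow(map) < 3) stop("underdetermined alignment: need >= 3 mapped atom pairs")
  P <- conf_xyz[map[, 1], , drop = FALSE]
  Q <- parent_xyz[map[, 2], , drop = FALSE]
  k <- kabsch(P, Q)
  list(xyz = apply_rigid(conf_xyz, k$R, k$t), rmsd = k$rmsd)
}

#' Rigid-body docking of a pose
#'
#' Derivative-free local optimization (Nelder-Mead) of the empirical binding
#' energy over the 6 rigid degrees of freedom, from the aligned start plus
#' `n_restarts` seeded random perturbations (up to `perturb_t` angstroms and
#' `perturb_r` degrees). The best pose never scores worse than the start.
#'
#' @param mol the ligand.
#' @param xyz starting full-atom pose.
#' @param pocket,hotspots,model the interaction field.
#' @param seed integer seed for the perturbation restarts.
#' @param n_restarts number of perturbed restarts (default 8).
#' @param perturb_t,perturb_r restart perturbation amplitudes (1 A, 15 deg).
#' @param maxit Nelder-Mead iteration budget per start.
#' @return list with `xyz`, `energy`, `clash` flag.
#' @export
rigid_dock <- function(mol, xyz, pocket, hotspots, model = default_energy_model(),
                       seed = 1L, n_restarts = 8L, perturb_t = 1.0, perturb_r = 15,
                       maxit = 150L) {
  hv <- heavy_atoms(mol)
  center <- colMeans(xyz[hv, , drop = FALSE])
  scorer <- make_pose_scorer(mol, xyz, pocket, hotspots, model)
  obj <- function(par) {
    scorer(R = rotation_from_vector(par[1:3]), t = par[4:6], center = center)
  }
  e0 <- obj(rep(0, 6))
  if (!is.finite(e0)) stop("non-finite starting energy")
  best_par <- rep(0, 6); best_e <- e0
  starts <- list(rep(0, 6))
  withr::with_seed(seed, {
    for (k in seq_len(n_restarts)) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- stats::runif(1, 0, perturb_r * pi / 180)
      tr <- stats::rnorm(3); tr <- tr / sqrt(sum(tr^2)) * stats::runif(1, 0, perturb_t)
      starts[[k + 1L]] <- c(ax * ang, tr)
    }
  })
  for (s in starts) {
    opt <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-8))
    if (opt$value < best_e) { best_e <- opt$value; best_par <- opt$par }
  }
  out_xyz <- apply_rigid_params(xyz, best_par, center)
  det <- binding_energy(mol, out_xyz, pocket, hotspots, model, detail = TRUE)
  list(xyz = out_xyz, energy = det$energy, clash = det$clash)
}

# Voxel keys occupied by heavy-atom spheres at vdW radii on a grid of given
# spacing anchored at the global origin (so two poses share the lattice).
.voxel_keys <- function(xyz, radii, spacing) {
  keys <- character(0)
  for (a in seq_len(nrow(xyz))) {
    r <- radii[a]
    lo <- floor((xyz[a, ] - r) / spacing)
    hi <- ceiling((xyz[a, ] + r) / spacing)
    gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
    cc <- expand.grid(x = gx, y = gy, z = gz)
    ctr <- (as.matrix(cc) + 0.5) * spacing
    inside <- rowSums(sweep(ctr, 2, xyz[a, ])^2) <= r^2
    if (any(inside)) {
      keys <- c(keys, paste(cc$x[inside], cc$y[inside], cc$z[inside], sep = ","))
    }
  }
  unique(keys)
}

#' Shape similarity of two poses
#'
#' Tanimoto coefficient of the occupied-voxel sets of the two poses:
#' heavy-atom spheres at van der Waals radii rasterized on a shared grid.
#' Symmetric in its arguments; 1 for identical voxel sets, 0 for disjoint.
#'
#' @param mol_a,xyz_a first molecule and full-atom pose.
#' @param mol_b,xyz_b second molecule and full-atom pose.
#' @param spacing grid spacing in angstroms (default 0.5).
#' @return numeric in `[0, 1]`.
#' @export
shape_similarity <- function(mol_a, xyz_a, mol_b, xyz_b, spacing = 0.5) {
  ha <- heavy_atoms(mol_a); hb <- heavy_atoms(mol_b)
  ka <- .voxel_keys(xyz_a[ha, , drop = FALSE], vdw_radius(mol_a$atoms$element[ha]), spacing)
  kb <- .voxel_keys(xyz_b[hb, , drop = FALSE], vdw_radius(mol_b$atoms$element[hb]), spacing)
  u <- length(union(ka, kb))
  if (u == 0) return(0)
  length(intersect(ka, kb)) / u
}
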