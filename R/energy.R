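# Empirical protein-ligand interaction field.
#
# The scoring function is an explicit surrogate on a kcal/mol-like scale:
# a soft 8-4 steric well over heavy-atom pairs, plus directional
# hydrogen-bond, aromatic and hydrophobic terms expressed through linear
# geometric switch functions. The same switches back the pharmacophore score,
# the PLI score and the interaction fingerprint, so every module shares one
# geometric definition of a contact.

#' Default empirical energy model
#'
#' All geometric windows (angstroms, degrees) and weights in one place.
#' Everything here is configuration: pass a modified copy to any scoring
#' function to change the field.
#'
#' @param ... named overrides of the default parameters.
#' @return an `fg_energy_model` list.
#' @export
default_energy_model <- function(...) {
  m <- list(
    # hydrogen bond: heavy-atom donor-acceptor distance window and
    # donor/acceptor alignment windows
    hb_dist = c(lo = 2.6, ideal = 2.9, hi = 3.4),
    hb_donor_angle_max = 60,     # deg between donor H direction and D->A
    hb_acceptor_angle_max = 90,  # deg between acceptor lone-pair dir and A->D
    # aromatic ring pairing: centroid distance + stacked / T-shaped windows
    ar_dist = c(lo = 3.5, ideal = 3.8, hi = 5.0),
    ar_stack_max = 40,           # deg, parallel-stacked branch
    ar_t_lo = 50, ar_t_hi = 90,  # deg, T-shaped branch
    # hydrophobic contact distance window
    hp_dist = c(lo = 3.0, ideal = 4.0, hi = 5.5),
    # pharmacophore / PLI weights per hotspot kind
    kind_weights = c(hb_donor = 1.0, hb_acceptor = 1.0,
                     aromatic_ring = 0.7, hydrophobic_patch = 0.3),
    # energy weights (kcal/mol-like, subtracted per satisfied contact).
    # Attraction comes almost entirely from the typed terms; the steric
    # well is kept very shallow (essentially a soft-core repulsion), so
    # untyped burial against a wall can never outweigh the pharmacophore
    energy_weights = c(hb = 3.0, aromatic = 2.0, hydrophobic = 0.4),
    steric_eps = 0.02,           # depth of the 8-4 well per heavy pair
    steric_cutoff = 6.0,         # pair list cutoff (anstroms)
    clash_ratio = 0.6,           # r below clash_ratio * vdw sum is penalized
    clash_k = 50,                # quadratic clash stiffness
    clash_energy_threshold = 25, # energies above this set the clash flag
    ionic_dist_max = 4.5         # opposite formal charges within this = ionic
  )
  dots <- list(...)
  for (nm in names(dots)) m[[nm]] <- dots[[nm]]
  structure(m, class = "fg_energy_model")
}

# Linear switch: 1 at `ideal`, falling linearly to 0 at `lo` and `hi`.
switch_linear <- function(x, lo, ideal, hi) {
  out <- numeric(length(x))
  left <- x >= lo & x < ideal
  right <- x >= ideal & x <= hi
  if (ideal > lo) out[left] <- (x[left] - lo) / (ideal - lo) else out[x == ideal] <- 1
  out[right] <- if (hi > ideal) (hi - x[right]) / (hi - ideal) else 1
  out[x == ideal] <- 1
  out
}

angle_deg <- function(u, v) {
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cu))) * 180 / pi
}

# Geometric satisfaction of a hydrogen bond between a donor (anchor + unit H
# direction) and an acceptor (anchor + lone-pair direction, may be zero).
hb_geometry <- function(donor_xyz, donor_dir, acc_xyz, acc_dir, model) {
  dvec <- acc_xyz - donor_xyz
  d <- sqrt(sum(dvec^2))
  g <- switch_linear(d, model$hb_dist["lo"], model$hb_dist["ideal"], model$hb_dist["hi"])
  if (g <= 0) return(0)
  a1 <- angle_deg(donor_dir, dvec)
  g <- g * max(0, 1 - a1 / model$hb_donor_angle_max)
  if (g <= 0) return(0)
  if (!any(is.na(acc_dir)) && sum(acc_dir^2) > 1e-9) {
    a2 <- angle_deg(acc_dir, -dvec)
    g <- g * max(0, 1 - a2 / model$hb_acceptor_angle_max)
  }
  unname(g)
}

# Aromatic ring pairing: distance switch times the better of the stacked and
# T-shaped orientation branches (normal sign is ignored).
aromatic_geometry <- function(c1, n1, c2, n2, model) {
  d <- sqrt(sum((c2 - c1)^2))
  g <- switch_linear(d, model$ar_dist["lo"], model$ar_dist["ideal"], model$ar_dist["hi"])
  if (g <= 0) return(0)
  a <- angle_deg(n1, n2)
  a <- min(a, 180 - a)
  g_stack <- max(0, 1 - a / model$ar_stack_max)
  g_t <- if (a >= model$ar_t_lo) {
    min(1, (a - model$ar_t_lo) / (model$ar_t_hi - model$ar_t_lo) * 2)  # saturates by 70 deg
  } else 0
  unname(g * max(g_stack, g_t))
}

hydrophobic_geometry <- function(p1, p2, model) {
  d <- sqrt(sum((p2 - p1)^2))
  unname(switch_linear(d, model$hp_dist["lo"], model$hp_dist["ideal"], model$hp_dist["hi"]))
}

# ---------------------------------------------------------------------------
# Contact enumeration: one row per (hotspot, ligand feature) pair with a
# positive geometric switch value. Single source of truth for the energy
# attractive terms, the pharmacophore score, the PLI score and the IFP.
contact_table <- function(features, hotspots, model) {
  rows <- list()
  if (!nrow(hotspots) || !nrow(features)) {
    return(tibble::tibble(hotspot = integer(), kind = character(), reskey = character(),
                          feature = integer(), g = numeric()))
  }
  hx <- hotspot_xyz(hotspots); hd <- hotspot_dir(hotspots)
  fx <- as.matrix(features[, c("x", "y", "z")])
  fd <- as.matrix(features[, c("dx", "dy", "dz")])
  for (h in seq_len(nrow(hotspots))) {
    hk <- hotspots$kind[h]
    partner_kind <- switch(hk,
      hb_donor = "hb_acceptor", hb_acceptor = "hb_donor",
      aromatic_ring = "aromatic_ring", hydrophobic_patch = "apolar")
    cand <- which(features$kind == partner_kind)
    for (f in cand) {
      g <- switch(hk,
        hb_donor = hb_geometry(hx[h, ], hd[h, ], fx[f, ], fd[f, ], model),
        hb_acceptor = hb_geometry(fx[f, ], fd[f, ], hx[h, ], hd[h, ], model),
        aromatic_ring = aromatic_geometry(hx[h, ], hd[h, ], fx[f, ], fd[f, ], model),
        hydrophobic_patch = hydrophobic_geometry(hx[h, ], fx[f, ], model))
      if (g > 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          hotspot = h, kind = hk, reskey = hotspots$reskey[h], feature = f, g = g)
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(hotspot = integer(), kind = character(), reskey = character(),
                          feature = integer(), g = numeric()))
  }
  dplyr::bind_rows(rows)
}

# Steric energy between ligand heavy atoms (xyz, subset rows) and pocket
# heavy atoms: soft 8-4 well plus quadratic clash penalty below
# clash_ratio * vdw sum. Returns list(energy, min_ratio).
steric_energy <- function(lig_xyz, lig_elements, pocket, model) {
  patoms <- pocket_atoms(pocket)
  keep <- patoms$element != "H"
  patoms <- patoms[keep, , drop = FALSE]
  pxyz <- cbind(patoms$x, patoms$y, patoms$z)
  if (!nrow(pxyz) || !nrow(lig_xyz)) return(list(energy = 0, min_ratio = Inf))
  d2 <- outer(rowSums(lig_xyz^2), rowSums(pxyz^2), "+") - 2 * lig_xyz %*% t(pxyz)
  d <- sqrt(pmax(d2, 1e-12))
  r0 <- outer(vdw_radius(lig_elements), vdw_radius(patoms$element), "+")
  sel <- d <= model$steric_cutoff
  if (!any(sel)) return(list(energy = 0, min_ratio = Inf))
  rr <- (r0[sel] / d[sel])
  # soften the inner wall: freeze rr at the clash boundary, clash term takes over
  rrc <- pmin(rr, 1 / model$clash_ratio)
  e_lj <- model$steric_eps * sum(rrc^8 - 2 * rrc^4)
  viol <- pmax(0, model$clash_ratio * r0[sel] - d[sel])
  e_clash <- model$clash_k * sum(viol^2)
  list(energy = e_lj + e_clash, min_ratio = min(d / r0))
}

# ---------------------------------------------------------------------------
# Fast pose scorers. make_flex_scorer() precomputes everything rigid about a
# (molecule, pocket, hotspot) triple — feature typing, pocket pair tables —
# and returns a closure evaluating the energy of ANY full-atom pose of the
# molecule. make_pose_scorer() wraps it for rigid moves of a fixed reference
# pose (docking). binding_energy() gives identical values (asserted in
# tests).
make_flex_scorer <- function(mol, pocket, hotspots, model) {
  hv <- heavy_atoms(mol)
  lig_r <- vdw_radius(mol$atoms$element[hv])
  patoms <- pocket_atoms(pocket)
  patoms <- patoms[patoms$element != "H", , drop = FALSE]
  pxyz <- cbind(patoms$x, patoms$y, patoms$z)
  p2 <- rowSums(pxyz^2)
  r0 <- outer(lig_r, vdw_radius(patoms$element), "+")
  inv_clash <- 1 / model$clash_ratio
  typing <- feature_typing(mol)

  hx <- if (nrow(hotspots)) hotspot_xyz(hotspots) else matrix(0, 0, 3)
  hd <- if (nrow(hotspots)) hotspot_dir(hotspots) else matrix(0, 0, 3)
  hkind <- hotspots$kind
  don_h <- which(hkind == "hb_donor")
  acc_h <- which(hkind == "hb_acceptor")
  ar_h <- which(hkind == "aromatic_ring")
  hp_h <- which(hkind == "hydrophobic_patch")

  w_hb <- model$energy_weights[["hb"]]
  w_ar <- model$energy_weights[["aromatic"]]
  w_hp <- model$energy_weights[["hydrophobic"]]
  sw <- function(d, win) switch_linear(d, win[["lo"]], win[["ideal"]], win[["hi"]])

  hb_grid <- function(dx_xyz, dx_dir, ax_xyz, ax_dir) {
    # donors rows, acceptors cols
    if (!nrow(dx_xyz) || !nrow(ax_xyz)) return(matrix(0, 0, 0))
    D2 <- outer(rowSums(dx_xyz^2), rowSums(ax_xyz^2), "+") - 2 * dx_xyz %*% t(ax_xyz)
    D <- sqrt(pmax(D2, 1e-12))
    G <- matrix(sw(as.vector(D), model$hb_dist), nrow(dx_xyz))
    if (!any(G > 0)) return(G)
    dot1 <- (dx_dir %*% t(ax_xyz)) - matrix(rowSums(dx_dir * dx_xyz), nrow(dx_xyz), nrow(ax_xyz))
    a1 <- acos(pmin(pmax(dot1 / D, -1), 1)) * 180 / pi
    G <- G * pmax(1 - a1 / model$hb_donor_angle_max, 0)
    ok_dir <- rowSums(ax_dir^2) > 1e-9 & !is.na(rowSums(ax_dir))
    dot2 <- (ax_dir %*% t(dx_xyz)) - matrix(rowSums(ax_dir * ax_xyz), nrow(ax_xyz), nrow(dx_xyz))
    a2 <- acos(pmin(pmax(t(dot2) / D, -1), 1)) * 180 / pi
    fac2 <- pmax(1 - a2 / model$hb_acceptor_angle_max, 0)
    fac2[, !ok_dir] <- 1
    G * fac2
  }

  function(xyz, components = FALSE) {
    lx <- xyz[hv, , drop = FALSE]
    d2 <- outer(rowSums(lx^2), p2, "+") - 2 * lx %*% t(pxyz)
    d <- sqrt(pmax(d2, 1e-12))
    sel <- d <= model$steric_cutoff
    e_st <- 0; min_ratio <- Inf
    if (any(sel)) {
      rr <- r0[sel] / d[sel]
      rrc <- pmin(rr, inv_clash)
      e_st <- model$steric_eps * sum(rrc^8 - 2 * rrc^4) +
        model$clash_k * sum(pmax(0, model$clash_ratio * r0[sel] - d[sel])^2)
      min_ratio <- min(d / r0)
    }
    pf <- position_features(typing, xyz)
    attract <- 0
    # a donor hydrogen engages at most one acceptor: every donor (pocket or
    # ligand side) contributes only its best-matched partner, which keeps a
    # single well-placed atom from being counted against several donors
    g1 <- hb_grid(hx[don_h, , drop = FALSE], hd[don_h, , drop = FALSE],
                  pf$acc_x, pf$acc_d)
    if (length(g1)) attract <- attract - w_hb * sum(apply(g1, 1, max))
    g2 <- hb_grid(pf$don_x, pf$don_d,
                  hx[acc_h, , drop = FALSE], hd[acc_h, , drop = FALSE])
    if (length(g2)) attract <- attract - w_hb * sum(apply(g2, 1, max))
    if (length(ar_h) && nrow(pf$ring_x)) {
      for (h in ar_h) {
        g_best <- 0
        for (f in seq_len(nrow(pf$ring_x))) {
          g_best <- max(g_best, aromatic_geometry(hx[h, ], hd[h, ],
                                                  pf$ring_x[f, ], pf$ring_d[f, ], model))
        }
        attract <- attract - w_ar * g_best
      }
    }
    if (length(hp_h) && nrow(pf$apolar_x)) {
      H <- hx[hp_h, , drop = FALSE]; P <- pf$apolar_x
      DH <- sqrt(pmax(outer(rowSums(H^2), rowSums(P^2), "+") - 2 * H %*% t(P), 1e-12))
      attract <- attract - w_hp * sum(sw(as.vector(DH), model$hp_dist))
    }
    e <- e_st + attract
    if (components) list(energy = e, steric = e_st, attract = attract,
                         min_ratio = min_ratio,
                         clash = e > model$clash_energy_threshold)
    else e
  }
}

make_pose_scorer <- function(mol, xyz_ref, pocket, hotspots, model) {
  fs <- make_flex_scorer(mol, pocket, hotspots, model)
  function(R = diag(3), t = c(0, 0, 0), center = c(0, 0, 0), components = FALSE) {
    xyz <- sweep(sweep(sweep(xyz_ref, 2, center) %*% t(R), 2, center, "+"), 2, t, "+")
    fs(xyz, components = components)
  }
}

#' Empirical binding energy of a pose
#'
#' `E = steric + sum(-w_hb g_hb) + sum(-w_ar g_ar) + sum(-w_hp g_hp) + clash`,
#' with geometric switches shared across the package. A ligand far from the
#' pocket scores exactly 0.
#'
#' @param mol the ligand molecule.
#' @param xyz full-atom pose coordinates.
#' @param pocket an `fg_pocket`.
#' @param hotspots hotspot tibble for the pocket.
#' @param model an `fg_energy_model`.
#' @param detail return a list with components instead of a bare number.
#' @return numeric energy (lower is better), or a list when `detail = TRUE`
#'   (`energy`, `steric`, `attract`, `clash` flag, `min_ratio`).
#' @export
binding_energy <- function(mol, xyz, pocket, hotspots, model = default_energy_model(),
                           detail = FALSE) {
  scorer <- make_pose_scorer(mol, xyz, pocket, hotspots, model)
  r <- scorer(components = TRUE)
  if (detail) r else r$energy
}

#' Protein-ligand interaction (PLI) score
#'
#' Weighted fraction of pocket hotspots satisfied by the pose: each hotspot
#' contributes its kind weight times the best geometric-switch value any
#' ligand feature achieves against it, normalized by the total hotspot
#' weight. Ranges 0 (no contact) to 1 (every hotspot ideally satisfied).
#'
#' @inheritParams binding_energy
#' @return numeric in `[0, 1]`.
#' @export
pli_score <- function(mol, xyz, pocket, hotspots, model = default_energy_model()) {
  if (!nrow(hotspots)) return(0)
  w <- model$kind_weights[hotspots$kind]
  feats <- ligand_features(mol, xyz)
  ct <- contact_table(feats, hotspots, model)
  best <- numeric(nrow(hotspots))
  if (nrow(ct)) {
    agg <- stats::aggregate(g ~ hotspot, data = ct, FUN = max)
    best[agg$hotspot] <- agg$g
  }
  sum(w * best) / sum(w)
}
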