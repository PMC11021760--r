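# Geometric assembly of grown-candidate poses.
#
# A child produced by direct linkage, ring fusion or spiro junction inherits
# its parent atoms' coordinates from the parent pose; the incoming fragment
# is attached rigidly at ideal bond geometry using a cached conformer of the
# fragment, with the junction torsion sampled on a fixed grid. Hydrogens are
# rebuilt on the assembled heavy skeleton. This is both much cheaper than
# re-embedding every candidate and keeps the inherited substructure exactly
# on its parent pose, which is what the subsequent alignment step would
# enforce anyway. Linker-rule children (two fixed parents bridged by a
# flexible linker) do not decompose this way and go through full embedding
# plus parent alignment instead.

# Rebuild hydrogen coordinates on a heavy-atom skeleton with standard
# geometry (tetrahedral / trigonal directions from the heavy neighbors).
place_hydrogens <- function(mol, heavy_xyz) {
  hv <- heavy_atoms(mol)
  xyz <- matrix(0, n_atoms(mol), 3)
  xyz[hv, ] <- heavy_xyz
  tet <- 109.47 * pi / 180
  for (a in hv) {
    nb <- atom_neighbors(mol, a)
    hs <- nb[mol$atoms$element[nb] == "H"]
    if (!length(hs)) next
    heavies <- nb[mol$atoms$element[nb] != "H"]
    bl <- covalent_radius(mol$atoms$element[a]) + covalent_radius("H")
    u <- if (length(heavies)) {
      t(vapply(heavies, function(b) unit(xyz[b, ] - xyz[a, ]), numeric(3)))
    } else matrix(0, 0, 3)
    base <- if (nrow(u)) -colSums(u) else c(0, 0, 1)
    if (sqrt(sum(base^2)) < 1e-6) {
      # linear arrangement of neighbors: any perpendicular
      base <- cross3(u[1, ], c(1, 0, 0))
      if (sqrt(sum(base^2)) < 1e-6) base <- cross3(u[1, ], c(0, 1, 0))
    }
    base <- unit(base)
    perp <- if (nrow(u)) unit(cross3(base, u[1, ])) else c(1, 0, 0)
    if (sqrt(sum(perp^2)) < 1e-6 && length(heavies) == 1) {
      # single heavy neighbor (e.g. aniline N, hydroxyl O): span the plane
      # of that neighbor's other substituents so conjugated H stay planar
      nb2 <- setdiff(atom_neighbors(mol, heavies[1]), a)
      nb2 <- nb2[mol$atoms$element[nb2] != "H"]
      if (length(nb2)) {
        v <- xyz[nb2[1], ] - xyz[heavies[1], ]
        perp <- unit(v - sum(v * base) * base)
      }
    }
    if (sqrt(sum(perp^2)) < 1e-6) perp <- unit(cross3(base, c(0, 0, 1)))
    perp2 <- cross3(base, perp)
    nh <- length(hs)
    dirs <- if (nh == 1) {
      list(base)
    } else if (nh == 2) {
      half <- tet / 2
      list(cos(half) * base + sin(half) * perp,
           cos(half) * base - sin(half) * perp)
    } else {
      cone <- pi - tet  # 70.5 deg off the base axis
      lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
        cos(cone) * base + sin(cone) * (cos(phi) * perp + sin(phi) * perp2)
      })
    }
    for (q in seq_len(nh)) xyz[hs[q], ] <- xyz[a, ] + unit(dirs[[q]]) * bl
  }
  xyz
}

# Cached embedded conformers of a fragment molecule.
.fragment_conformers <- function(frag, cache, seed, n = 2L) {
  key <- frag$id
  if (!is.null(cache[[key]])) return(cache[[key]])
  confs <- generate_conformers(frag$mol, n = n, seed = derive_seed(seed, "frag", key))
  cache[[key]] <- confs
  confs
}

# Child heavy-atom index layout after graph surgery (heavy order preserved):
# parent heavies first, then the fragment heavies that survived the rule.
.child_layout <- function(n_parent_heavy, frag_mol, dropped_frag_heavy = integer()) {
  nf <- length(heavy_atoms(frag_mol))
  kept <- setdiff(seq_len(nf), dropped_frag_heavy)
  list(parent = seq_len(n_parent_heavy),
       frag = n_parent_heavy + seq_along(kept),
       frag_src = kept)
}

# Atom set that rotates with the junction torsion of a direct-linkage
# child: every atom not inherited from the parent (fragment heavies plus
# their hydrogens), identified from provenance and adjacency.
torsion_movers <- function(child_mol) {
  prov <- child_mol$atoms$provenance
  new_heavy <- which(prov == "new" & child_mol$atoms$element != "H")
  hs <- which(child_mol$atoms$element == "H")
  h_new <- hs[vapply(hs, function(h) {
    nb <- atom_neighbors(child_mol, h)
    length(nb) == 1 && nb %in% new_heavy
  }, logical(1))]
  c(new_heavy, h_new)
}

# Local optimization of a direct-linkage child over 6 rigid DOF plus the
# junction torsion. `axis_atoms` = c(parent attachment atom, fragment
# attachment atom) in child indexing.
dock_with_torsion <- function(mol, xyz, axis_atoms, movers, flex,
                              maxit = 250L) {
  hv <- heavy_atoms(mol)
  center <- colMeans(xyz[hv, , drop = FALSE])
  pose_of <- function(par) {
    X <- xyz
    ax <- X[axis_atoms[2], ] - X[axis_atoms[1], ]
    X[movers, ] <- rotate_about_axis(X[movers, , drop = FALSE], ax,
                                     X[axis_atoms[1], ], par[7])
    apply_rigid_params(X, par[1:6], center)
  }
  obj <- function(par) flex(pose_of(par))
  e0 <- obj(rep(0, 7))
  opt <- stats::optim(rep(0, 7), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  if (opt$value < e0) list(xyz = pose_of(opt$par), energy = opt$value)
  else list(xyz = xyz, energy = e0)
}

# Assemble candidate poses for a direct-linkage child.
# parent_pose: full-atom parent pose; ai: parent attachment atom (full idx);
# bi: fragment attachment atom (full idx). Torsion sampled on a fixed grid,
# one pose per (parent open H direction x fragment conformer x torsion).
assemble_direct <- function(child_mol, parent_mol, parent_pose, ai, frag, bi,
                            frag_confs, n_torsions = 6L) {
  hv_p <- heavy_atoms(parent_mol)
  hv_f <- heavy_atoms(frag$mol)
  lay <- .child_layout(length(hv_p), frag$mol)
  pa_pos <- parent_pose[ai, ]
  h_dirs <- {
    nb <- atom_neighbors(parent_mol, ai)
    hs <- nb[parent_mol$atoms$element[nb] == "H"]
    lapply(hs, function(h) unit(parent_pose[h, ] - pa_pos))
  }
  if (!length(h_dirs)) return(list())
  blen <- covalent_radius(parent_mol$atoms$element[ai]) +
    covalent_radius(frag$mol$atoms$element[bi])
  out <- list()
  for (d in h_dirs) {
    target <- pa_pos + d * blen
    for (cf in frag_confs) {
      fb_pos <- cf[bi, ]
      nbf <- atom_neighbors(frag$mol, bi)
      hf <- nbf[frag$mol$atoms$element[nbf] == "H"]
      if (!length(hf)) next
      fdir <- unit(cf[hf[1], ] - fb_pos)
      R <- .rotation_between(fdir, -d)
      Xf <- sweep(sweep(cf, 2, fb_pos) %*% t(R), 2, target, "+")
      for (k in seq_len(n_torsions)) {
        ang <- 2 * pi * (k - 1) / n_torsions
        Xk <- rotate_about_axis(Xf, d, target, ang)
        heavy_child <- rbind(parent_pose[hv_p, , drop = FALSE],
                             Xk[hv_f, , drop = FALSE])
        out[[length(out) + 1L]] <- place_hydrogens(child_mol, heavy_child)
      }
    }
  }
  out
}

# Assemble poses for a ring-fusion child: the fragment conformer is anchored
# so its fused-bond atoms coincide with the parent bond atoms, then spun
# about the fused bond axis on a grid.
assemble_fuse <- function(child_mol, parent_mol, parent_pose, bond_a, frag,
                          mapping, frag_confs, n_spins = 4L) {
  hv_p <- heavy_atoms(parent_mol)
  hv_f <- heavy_atoms(frag$mol)
  ba <- parent_mol$bonds[bond_a, ]
  a1 <- ba$i; a2 <- ba$j          # full indices in parent
  b1 <- mapping[1]; b2 <- mapping[2]  # full indices in fragment (deleted atoms)
  dropped <- match(c(b1, b2), hv_f)
  lay <- .child_layout(length(hv_p), frag$mol, dropped)
  p1 <- parent_pose[a1, ]; p2 <- parent_pose[a2, ]
  axis <- unit(p2 - p1)
  out <- list()
  for (cf in frag_confs) {
    q1 <- cf[b1, ]; q2 <- cf[b2, ]
    R <- .rotation_between(unit(q2 - q1), axis)
    Xf <- sweep(sweep(cf, 2, q1) %*% t(R), 2, p1, "+")
    for (k in seq_len(n_spins)) {
      ang <- 2 * pi * (k - 1) / n_spins
      Xk <- rotate_about_axis(Xf, axis, p1, ang)
      heavy_child <- rbind(parent_pose[hv_p, , drop = FALSE],
                           Xk[hv_f[lay$frag_src], , drop = FALSE])
      out[[length(out) + 1L]] <- place_hydrogens(child_mol, heavy_child)
    }
  }
  out
}

# Assemble poses for a spiro child: the fragment's shared atom sits on the
# parent atom; the fragment ring is oriented into the parent atom's freed
# hydrogen directions (both assignments tried).
assemble_spiro <- function(child_mol, parent_mol, parent_pose, atom_a, frag,
                           atom_b, frag_confs) {
  hv_p <- heavy_atoms(parent_mol)
  hv_f <- heavy_atoms(frag$mol)
  dropped <- match(atom_b, hv_f)
  lay <- .child_layout(length(hv_p), frag$mol, dropped)
  a_pos <- parent_pose[atom_a, ]
  nb <- atom_neighbors(parent_mol, atom_a)
  hs <- nb[parent_mol$atoms$element[nb] == "H"]
  if (length(hs) < 2) return(list())
  hdir <- lapply(hs[1:2], function(h) unit(parent_pose[h, ] - a_pos))
  out <- list()
  for (cf in frag_confs) {
    b_pos <- cf[atom_b, ]
    nbf <- atom_neighbors(frag$mol, atom_b)
    ring_nb <- nbf[frag$mol$atoms$element[nbf] != "H"]
    if (length(ring_nb) < 2) next
    v <- lapply(ring_nb[1:2], function(x) unit(cf[x, ] - b_pos))
    for (assign in list(c(1, 2), c(2, 1))) {
      # best rotation mapping the two fragment ring directions onto the two
      # freed hydrogen directions (Kabsch on the direction vectors)
      P <- rbind(v[[assign[1]]], v[[assign[2]]], unit(cross3(v[[assign[1]]], v[[assign[2]]])))
      Q <- rbind(hdir[[1]], hdir[[2]], unit(cross3(hdir[[1]], hdir[[2]])))
      fit <- kabsch(P, Q)
      Xf <- sweep((cf - matrix(b_pos, nrow(cf), 3, byrow = TRUE)) %*% fit$R,
                  2, a_pos, "+")
      heavy_child <- rbind(parent_pose[hv_p, , drop = FALSE],
                           Xf[hv_f[lay$frag_src], , drop = FALSE])
      out[[length(out) + 1L]] <- place_hydrogens(child_mol, heavy_child)
    }
  }
  out
}
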