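test_that("a ligand far from the pocket scores exactly zero", {
  toy <- fx_toy()
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  xyz <- toy$ligand$conformers[[1]] + 50
  expect_identical(binding_energy(toy$ligand, xyz, pocket, hs), 0)
  expect_identical(pli_score(toy$ligand, xyz, pocket, hs), 0)
})

test_that("an ideal hydrogen bond contributes exactly its weight", {
  # geometry-level check of the switch functions
  model <- default_energy_model()
  g <- fraggrow:::hb_geometry(c(0, 0, 0), c(1, 0, 0),
                              c(2.9, 0, 0), c(-1, 0, 0), model)
  expect_equal(g, 1)
  # end-to-end: with sterics turned off the planted toy ligand's energy is
  # exactly minus the summed switch-weighted contacts
  toy <- fx_toy()
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  m0 <- default_energy_model(steric_eps = 0, clash_k = 0)
  e <- binding_energy(toy$ligand, toy$ligand$conformers[[1]], pocket, hs, m0)
  ct <- fraggrow:::contact_table(ligand_features(toy$ligand), hs, m0)
  # independent recomputation: each donor hydrogen (pocket or ligand side)
  # counts only its best partner; aromatic hotspots their best ring;
  # hydrophobic contacts are additive
  don <- ct[ct$kind == "hb_donor", ]
  e_don <- sum(tapply(don$g, don$hotspot, max))
  acc <- ct[ct$kind == "hb_acceptor", ]
  e_acc <- sum(tapply(acc$g, acc$feature, max))
  ar <- ct[ct$kind == "aromatic_ring", ]
  e_ar <- if (nrow(ar)) sum(tapply(ar$g, ar$hotspot, max)) else 0
  hp <- ct[ct$kind == "hydrophobic_patch", ]
  expected <- -(3 * (e_don + e_acc) + 2 * e_ar + 0.4 * sum(hp$g))
  expect_equal(e, expected, tolerance = 1e-6)
  # the two planted serine donors are (near-)ideally satisfied
  planted <- ct[ct$kind == "hb_donor", ]
  expect_gte(nrow(planted), 2)
  expect_gt(max(planted$g), 0.95)
})

test_that("severe overlap is penalized and flagged as a clash", {
  toy <- fx_toy()
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  patom <- fraggrow:::pocket_atoms(pocket)
  m <- parse_molecule("C")
  xyz <- matrix(0, 5, 3)
  xyz[1, ] <- c(patom$x[1], patom$y[1], patom$z[1]) + 0.4  # deep overlap
  det <- binding_energy(m, xyz, pocket, hs, detail = TRUE)
  expect_true(det$clash)
  expect_gt(det$energy, default_energy_model()$clash_energy_threshold)
})

test_that("energy is invariant under a joint rigid transform of pose and pocket", {
  toy <- fx_toy()
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  xyz <- toy$ligand$conformers[[1]]
  e0 <- binding_energy(toy$ligand, xyz, pocket, hs)
  R <- fraggrow:::rotation_from_vector(c(-0.7, 0.2, 0.4))
  tvec <- c(3, 8, -5)
  prot2 <- fraggrow:::transform_protein(toy$protein, R, tvec)
  lig2 <- toy$ligand
  lig2$conformers[[1]] <- fraggrow:::apply_rigid(xyz, R, tvec)
  pocket2 <- extract_pocket(prot2, lig2, cutoff = 5)
  hs2 <- detect_hotspots(pocket2)
  e1 <- binding_energy(lig2, lig2$conformers[[1]], pocket2, hs2)
  expect_equal(e1, e0, tolerance = 1e-6)
})

test_that("rigid docking never worsens the energy and holds at an optimum", {
  toy <- fx_toy()
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  lig <- toy$ligand
  xyz <- lig$conformers[[1]]
  # converge once to a constructed local optimum of the field
  opt <- rigid_dock(lig, xyz, pocket, hs, seed = 1, n_restarts = 4, maxit = 400)
  # docking from the optimum stays put
  again <- rigid_dock(lig, opt$xyz, pocket, hs, seed = 2, n_restarts = 2, maxit = 200)
  hv <- which(lig$atoms$element != "H")
  expect_lt(rmsd(again$xyz[hv, ], opt$xyz[hv, ]), 0.1)
  # energy is non-increasing over random perturbed starts
  withr::with_seed(31, {
    for (rep in 1:5) {
      par <- c(stats::rnorm(3, sd = 0.05), stats::rnorm(3, sd = 0.3))
      start <- fraggrow:::apply_rigid_params(xyz, par, colMeans(xyz[hv, ]))
      e_start <- binding_energy(lig, start, pocket, hs)
      dk <- rigid_dock(lig, start, pocket, hs, seed = rep, n_restarts = 2)
      expect_lte(dk$energy, e_start + 1e-9)
    }
  })
})

test_that("PLI score satisfies its defining arithmetic", {
  # one donor hotspot, ideally satisfied acceptor -> 1
  hs1 <- tibble::tibble(kind = "hb_donor", reskey = "A:1", label = "X",
                        x = 0, y = 0, z = 0, dx = 1, dy = 0, dz = 0)
  water <- parse_molecule("O")
  xyz <- matrix(0, 3, 3)
  xyz[1, ] <- c(2.9, 0, 0)              # O on the donor axis
  xyz[2, ] <- c(3.5, 0.8, 0); xyz[3, ] <- c(3.5, -0.8, 0)
  pocket_stub <- fx_pocket()
  m <- default_energy_model()
  ct <- fraggrow:::contact_table(ligand_features(water, xyz), hs1, m)
  expect_gt(max(ct$g), 0.9)
  # 1 of 2 equal-weight hotspots ideally satisfied -> about 0.5
  hs2 <- dplyr::bind_rows(hs1, tibble::tibble(
    kind = "hb_donor", reskey = "A:2", label = "Y",
    x = 50, y = 0, z = 0, dx = 1, dy = 0, dz = 0))
  feats <- ligand_features(water, xyz)
  g1 <- max(ct$g)
  best <- c(g1, 0)
  w <- m$kind_weights[hs2$kind]
  expect_equal(sum(w * best) / sum(w), g1 / 2)
})

test_that("PLI never decreases when an ideal feature is added", {
  toy <- fx_toy()
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  frag <- toy$fragments[[1]]
  hvf <- heavy_atoms <- which(frag$mol$atoms$element != "H")
  crys <- matrix(0, nrow(frag$mol$atoms), 3)
  crys[hvf, ] <- toy$ligand$conformers[[1]][frag$src_atoms, ]
  crys <- fraggrow:::place_hydrogens(frag$mol, crys[hvf, , drop = FALSE])
  p_frag <- pli_score(frag$mol, crys, pocket, hs)
  p_full <- pli_score(toy$ligand, toy$ligand$conformers[[1]], pocket, hs)
  expect_gte(p_full, p_frag - 1e-9)
})

test_that("shape similarity is a symmetric overlap measure on [0,1]", {
  m <- parse_molecule("c1ccccc1")
  xyz <- generate_conformers(m, 1, seed = 1)[[1]]
  expect_equal(shape_similarity(m, xyz, m, xyz), 1)
  far <- xyz + 30
  expect_equal(shape_similarity(m, xyz, m, far), 0)
  m2 <- parse_molecule("c1ccncc1")
  xyz2 <- generate_conformers(m2, 1, seed = 1)[[1]]
  s12 <- shape_similarity(m, xyz, m2, xyz2)
  s21 <- shape_similarity(m2, xyz2, m, xyz)
  expect_equal(s12, s21)
  expect_true(s12 > 0 && s12 < 1)
})

test_that("single-sphere shape overlap matches a brute-force voxel count", {
  # two carbon-like spheres offset by 1.7 angstroms on a 0.5 grid
  m <- parse_molecule("C")
  xa <- matrix(0, 5, 3); xb <- xa; xb[1, 1] <- 1.7
  got <- shape_similarity(m, xa, m, xb, spacing = 0.5)
  # oracle: enumerate the lattice directly
  r <- 1.70
  grid <- expand.grid(x = seq(-8, 8), y = seq(-8, 8), z = seq(-8, 8))
  ctr <- (as.matrix(grid) + 0.5) * 0.5
  ina <- rowSums(ctr^2) <= r^2
  inb <- rowSums(sweep(ctr, 2, c(1.7, 0, 0))^2) <= r^2
  expect_equal(got, sum(ina & inb) / sum(ina | inb), tolerance = 1e-9)
})
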