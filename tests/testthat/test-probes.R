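test_that("probe placement realizes complementary pairings at H-bond geometry", {
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  pyr <- parse_molecule("c1ccncc1")
  pl <- enumerate_probe_placements(pyr, pocket, hs, n_conformers = 1, seed = 3)
  expect_gt(nrow(pl), 0)
  donors <- which(hs$kind == "hb_donor")
  n_idx <- which(pyr$atoms$element == "N")
  hits <- 0
  for (q in seq_len(nrow(pl))) {
    if (!pl$hotspot[q] %in% donors) next
    anchor <- as.numeric(hs[pl$hotspot[q], c("x", "y", "z")])
    d <- sqrt(sum((pl$pose[[q]][n_idx, ] - anchor)^2))
    if (d >= 2.6 && d <= 3.4) hits <- hits + 1
  }
  expect_gt(hits, 0)
  # determinism
  pl2 <- enumerate_probe_placements(pyr, pocket, hs, n_conformers = 1, seed = 3)
  expect_identical(pl, pl2)
  # sorted by pharmacophore score, ties by energy
  expect_true(all(diff(round(pl$pharmacophore_score, 6)) <= 0))
})

test_that("featureless probes are unplaceable and non-complementary sets warn", {
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  expect_error(enumerate_probe_placements(parse_molecule("CCC"), pocket, hs),
               "unplaceable")
  # donor/acceptor-only hotspots vs a pure aromatic probe: no pairing
  hs_polar <- hs[hs$kind %in% c("hb_donor", "hb_acceptor"), ]
  benz <- parse_molecule("c1ccccc1")
  expect_warning(out <- enumerate_probe_placements(benz, pocket, hs_polar,
                                                   n_conformers = 1, seed = 1),
                 "no feasible")
  expect_equal(nrow(out), 0)
})

test_that("placements are equivariant under rigid motion of the complex", {
  toy <- fx_toy()
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  pyr <- parse_molecule("c1ccncc1")
  pl <- enumerate_probe_placements(pyr, pocket, hs, n_conformers = 1, seed = 5)
  R <- fraggrow:::rotation_from_vector(c(0.2, 0.9, -0.3))
  tvec <- c(-6, 2, 9)
  prot2 <- fraggrow:::transform_protein(toy$protein, R, tvec)
  lig2 <- toy$ligand
  lig2$conformers[[1]] <- fraggrow:::apply_rigid(lig2$conformers[[1]], R, tvec)
  pocket2 <- extract_pocket(prot2, lig2, cutoff = 5)
  hs2 <- detect_hotspots(pocket2)
  pl2 <- enumerate_probe_placements(pyr, pocket2, hs2, n_conformers = 1, seed = 5)
  expect_equal(nrow(pl2), nrow(pl))
  expect_equal(pl2$pharmacophore_score, pl$pharmacophore_score, tolerance = 1e-6)
  expect_equal(pl2$binding_energy, pl$binding_energy, tolerance = 1e-5)
  for (q in seq_len(min(5, nrow(pl)))) {
    expect_equal(pl2$pose[[q]], fraggrow:::apply_rigid(pl$pose[[q]], R, tvec),
                 tolerance = 1e-5)
  }
})

test_that("the default refiner improves energy inside its trust region", {
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  pyr <- parse_molecule("c1ccncc1")
  pl <- enumerate_probe_placements(pyr, pocket, hs, n_conformers = 1, seed = 2)
  pose <- pl$pose[[1]]
  e0 <- binding_energy(pyr, pose, pocket, hs)
  ref <- default_refine(pyr, pose, pocket, hs)
  expect_lte(ref$energy, e0 + 1e-9)
  # refining the refined pose changes little (near a fixed point)
  ref2 <- default_refine(pyr, ref$xyz, pocket, hs)
  hv <- which(pyr$atoms$element != "H")
  expect_lt(rmsd(ref2$xyz[hv, ], ref$xyz[hv, ]), 0.3)
  # trust region: the centroid never moves more than 2 angstroms
  expect_lte(sqrt(sum((colMeans(ref$xyz[hv, ]) - colMeans(pose[hv, ]))^2)), 2 + 1e-6)
  # energy non-increase over a sweep of perturbed poses
  withr::with_seed(12, {
    for (rep in 1:10) {
      par <- c(stats::rnorm(3, sd = 0.1), stats::rnorm(3, sd = 0.3))
      start <- fraggrow:::apply_rigid_params(pose, par, colMeans(pose[hv, ]))
      es <- binding_energy(pyr, start, pocket, hs)
      rr <- default_refine(pyr, start, pocket, hs)
      expect_lte(rr$energy, es + 1e-9)
    }
  })
})

test_that("an external refiner is interchangeable through the contract", {
  skip_on_os("windows")
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  pyr <- parse_molecule("c1ccncc1")
  pl <- enumerate_probe_placements(pyr, pocket, hs, n_conformers = 1, seed = 2)
  pose <- pl$pose[[1]]
  # mock external program: copies the input ligand to the output unchanged
  mock <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "cp \"$1\" \"$3\""), mock)
  Sys.chmod(mock, "0755")
  ref <- xtb_refiner(mock)
  out <- ref$refine(pyr, pose, pocket, hs)
  expect_equal(nrow(out$xyz), nrow(pose))
  expect_lte(out$energy, binding_energy(pyr, pose, pocket, hs) + 1e-6)
  # a failing external program degrades gracefully to the input pose
  bad <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "exit 3"), bad)
  Sys.chmod(bad, "0755")
  expect_warning(out2 <- xtb_refiner(bad)$refine(pyr, pose, pocket, hs), "failed")
  expect_equal(out2$xyz, pose)
})

test_that("probe selection dedups poses and honors ranking semantics", {
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  pyr <- parse_molecule("c1ccncc1")
  pl <- enumerate_probe_placements(pyr, pocket, hs, n_conformers = 1, seed = 4)
  # duplicate every pose shifted by 0.2 angstroms: dedup halves the pool
  dup <- pl
  dup$pose <- lapply(dup$pose, function(p) p + 0.2 / sqrt(3))
  both <- dplyr::bind_rows(pl, dup)
  sel <- select_probes(both, k = nrow(both))
  expect_lte(nrow(sel), nrow(pl))
  # k larger than pool warns and returns the pool
  expect_warning(sel2 <- select_probes(pl[1:2, ], k = 10), "only")
  expect_equal(nrow(sel2), nrow(select_probes(pl[1:2, ], k = 2)))
  # zero energy weight reduces to pure pharmacophore ranking
  sel3 <- select_probes(pl, k = nrow(pl), energy_weight = 0, dedup_rmsd = 0)
  expect_true(all(diff(round(sel3$pharmacophore_score, 6)) <= 0))
  expect_error(select_probes(pl[0, ], k = 1), "empty")
})
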