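test_that("pocket extraction selects contact-shell residues, monotone in cutoff", {
  toy <- fx_toy()
  p5 <- extract_pocket(toy$protein, toy$ligand, cutoff = 5)
  expect_s3_class(p5, "fg_pocket")
  expect_gte(length(p5$residues), 2)
  p8 <- extract_pocket(toy$protein, toy$ligand, cutoff = 8)
  expect_true(all(p5$residues %in% p8$residues))
  p12 <- extract_pocket(toy$protein, toy$ligand, cutoff = 12)
  expect_true(all(p8$residues %in% p12$residues))
  expect_error(extract_pocket(toy$protein, toy$ligand, cutoff = 0.1), "outside protein")
})

test_that("hotspot typing finds side-chain donors/acceptors and backbone sites", {
  hs <- fx_hotspots()
  # the toy pocket plants lysine donors at the ligand acceptors
  expect_true(any(hs$kind == "hb_donor" & grepl("^NZ-", hs$label)))
  # a ligand with a donor but no acceptor gets an aspartate carboxylate
  toy2 <- fx_donor_toy()
  hs_d <- detect_hotspots(extract_pocket(toy2$protein, toy2$ligand, 5))
  expect_true(any(hs_d$kind == "hb_acceptor" & hs_d$label %in% c("OD1", "OD2")))
  # backbone carbonyl acceptors and amide donors are typed on every residue
  expect_true(any(hs$kind == "hb_acceptor" & hs$label == "O"))
  expect_true(any(hs$kind == "hb_donor" & grepl("^N-", hs$label)))
  # direction vectors are unit norm where present
  d <- as.matrix(hs[, c("dx", "dy", "dz")])
  ok <- !is.na(d[, 1])
  expect_equal(sqrt(rowSums(d[ok, , drop = FALSE]^2)), rep(1, sum(ok)), tolerance = 1e-6)
})

test_that("pockets without aromatic side chains yield no aromatic hotspots", {
  gly <- fx_polar_toy()
  expect_false("PHE" %in% gly$protein$atoms$resname)
  pocket <- extract_pocket(gly$protein, gly$ligand, cutoff = 6)
  hs <- detect_hotspots(pocket)
  expect_false(any(hs$kind == "aromatic_ring"))
})

test_that("hotspots co-transform under a rigid motion of the whole complex", {
  toy <- fx_toy()
  hs <- fx_hotspots()
  R <- fraggrow:::rotation_from_vector(c(0.3, -0.5, 0.8))
  tvec <- c(4, -2, 7)
  prot2 <- fraggrow:::transform_protein(toy$protein, R, tvec)
  lig2 <- toy$ligand
  lig2$conformers[[1]] <- fraggrow:::apply_rigid(lig2$conformers[[1]], R, tvec)
  hs2 <- detect_hotspots(extract_pocket(prot2, lig2, cutoff = 5))
  expect_equal(nrow(hs2), nrow(hs))
  expect_equal(as.matrix(hs2[, c("x", "y", "z")]),
               fraggrow:::apply_rigid(as.matrix(hs[, c("x", "y", "z")]), R, tvec),
               tolerance = 1e-6, ignore_attr = TRUE)
  d1 <- as.matrix(hs[, c("dx", "dy", "dz")])
  d2 <- as.matrix(hs2[, c("dx", "dy", "dz")])
  ok <- !is.na(d1[, 1])
  expect_equal(d2[ok, ], d1[ok, , drop = FALSE] %*% R, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("planted donor hotspots point toward the pocket interior", {
  toy <- fx_toy()
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  planted <- hs[hs$kind == "hb_donor" & hs$label == "NZ-HZ1", ]
  lig_ctr <- colMeans(toy$ligand$conformers[[1]])
  for (i in seq_len(nrow(planted))) {
    to_center <- unname(lig_ctr - as.numeric(planted[i, c("x", "y", "z")]))
    dot <- sum(to_center * as.numeric(planted[i, c("dx", "dy", "dz")]))
    expect_gt(dot, 0)
  }
})

test_that("hotspot PDB dump writes one pseudo-atom per hotspot", {
  hs <- fx_hotspots()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_hotspots_pdb(hs, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^HETATM", lines)), nrow(hs))
})
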