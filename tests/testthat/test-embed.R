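test_that("conformer generation is bitwise deterministic under a fixed seed", {
  m <- parse_molecule("CCCCO")
  a <- generate_conformers(m, n = 4, seed = 42)
  b <- generate_conformers(m, n = 4, seed = 42)
  expect_identical(a, b)
  c2 <- generate_conformers(m, n = 4, seed = 43)
  expect_false(identical(a, c2))
})

test_that("rigid molecules collapse to one conformer, flexible chains do not", {
  benz <- parse_molecule("c1ccccc1")
  expect_length(generate_conformers(benz, n = 10, seed = 1), 1)
  hexane <- parse_molecule("CCCCCC")
  expect_gt(length(generate_conformers(hexane, n = 20, seed = 1)), 1)
})

test_that("surviving conformers are mutually distinct above the dedup radius", {
  m <- parse_molecule("CCCCCC")
  confs <- generate_conformers(m, n = 10, seed = 7)
  hv <- which(m$atoms$element != "H")
  if (length(confs) > 1) {
    for (i in seq_along(confs)[-1]) {
      for (j in seq_len(i - 1)) {
        expect_gte(fraggrow:::superposed_rmsd(confs[[i]][hv, ], confs[[j]][hv, ]), 0.5)
      }
    }
  }
})

test_that("embedded geometry is chemically sane", {
  for (s in c("c1ccccc1", "C1CCCCC1", "c1ccc2ccccc2c1", "CC(=O)NC",
              "Oc1ccc(cc1)c1ccncc1", "C1CCC2(CC1)CCCC2")) {
    m <- parse_molecule(s)
    X <- generate_conformers(m, 1, seed = 3)[[1]]
    b <- m$bonds
    lens <- sqrt(rowSums((X[b$i, , drop = FALSE] - X[b$j, , drop = FALSE])^2))
    expect_true(all(lens > 0.85 & lens < 1.75), info = s)
    hv <- which(m$atoms$element != "H")
    if (length(hv) > 4) {
      D <- as.matrix(dist(X[hv, ])); diag(D) <- Inf
      expect_gt(min(D), 1.1)
    }
  }
})

test_that("aromatic rings come out planar", {
  m <- parse_molecule("c1ccccc1")
  X <- generate_conformers(m, 1, seed = 5)[[1]]
  hv <- 1:6
  ctr <- colMeans(X[hv, ])
  expect_lt(svd(sweep(X[hv, ], 2, ctr))$d[3], 0.05)
})
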