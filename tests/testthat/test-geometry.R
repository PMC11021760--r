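random_rigid <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- fraggrow:::rotation_from_vector(ax * stats::runif(1, 0, pi))
  list(R = R, t = stats::rnorm(3, sd = 5))
}

test_that("Kabsch removes arbitrary rigid transforms exactly", {
  withr::with_seed(4, {
    for (rep in 1:10) {
      P <- matrix(stats::rnorm(30), 10, 3)
      tr <- random_rigid()
      Q <- fraggrow:::apply_rigid(P, tr$R, tr$t)
      fit <- kabsch(P, Q)
      expect_lt(fit$rmsd, 1e-8)
      expect_equal(det(fit$R), 1, tolerance = 1e-9)
    }
  })
})

test_that("symmetry RMSD respects graph automorphisms", {
  benz <- parse_molecule("c1ccccc1")
  xyz <- generate_conformers(benz, 1, seed = 3)[[1]]
  # identity
  expect_equal(symmetry_rmsd(benz, xyz, xyz), 0)
  # uniform translation by (1,0,0) gives exactly 1
  expect_equal(symmetry_rmsd(benz, xyz, sweep(xyz, 2, c(1, 0, 0), "+")), 1, tolerance = 1e-9)
  # 60 degree in-plane rotation about the ring centroid is an automorphism
  hv <- which(benz$atoms$element != "H")
  ctr <- colMeans(xyz[hv, ])
  sv <- svd(sweep(xyz[hv, ], 2, ctr))
  normal <- sv$v[, 3]
  rot <- fraggrow:::rotate_about_axis(xyz, normal, ctr, pi / 3)
  expect_lt(symmetry_rmsd(benz, xyz, rot), 0.05)
  # ... but a plain per-index RMSD is far from zero
  expect_gt(rmsd(xyz[hv, ], rot[hv, ]), 1)
})

test_that("symmetry RMSD is a pseudometric on random pose triples", {
  m <- parse_molecule("Cc1ccccc1")
  base <- generate_conformers(m, 1, seed = 9)[[1]]
  withr::with_seed(20, {
    poses <- lapply(1:3, function(i) {
      tr <- random_rigid()
      fraggrow:::apply_rigid(base, tr$R, tr$t)
    })
    d12 <- symmetry_rmsd(m, poses[[1]], poses[[2]])
    d13 <- symmetry_rmsd(m, poses[[1]], poses[[3]])
    d23 <- symmetry_rmsd(m, poses[[2]], poses[[3]])
    expect_gte(d12, 0)
    expect_equal(d12, symmetry_rmsd(m, poses[[2]], poses[[1]]), tolerance = 1e-9)
    expect_lte(d13, d12 + d23 + 1e-9)
  })
})

test_that("alignment to parent removes rigid motion and flags degeneracy", {
  m <- parse_molecule("c1ccncc1")
  xyz <- generate_conformers(m, 1, seed = 2)[[1]]
  tr <- withr::with_seed(8, random_rigid())
  moved <- fraggrow:::apply_rigid(xyz, tr$R, tr$t)
  hv <- which(m$atoms$element != "H")
  map <- cbind(hv, hv)
  al <- align_to_parent(moved, xyz, map)
  expect_lt(al$rmsd, 1e-6)
  expect_equal(al$xyz[hv, ], xyz[hv, ], tolerance = 1e-6)
  expect_error(align_to_parent(moved, xyz, map[1:2, ]), "underdetermined")
})
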