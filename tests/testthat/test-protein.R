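test_that("PDB write/read round trip preserves coordinates to PDB precision", {
  toy <- fx_toy()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_protein(toy$protein, path)
  p2 <- read_protein(path)
  expect_equal(nrow(p2$atoms), nrow(toy$protein$atoms))
  expect_equal(length(unique(p2$atoms$reskey)), length(unique(toy$protein$atoms$reskey)))
  expect_equal(fraggrow:::protein_xyz(p2), fraggrow:::protein_xyz(toy$protein),
               tolerance = 1e-3)
})

test_that("HETATM-only files are a format error; waters are dropped", {
  het <- c(
    "HETATM    1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(het, f)
  expect_error(read_protein(f), "no ATOM records")

  wat <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  O   HOH A   2       5.000   0.000   0.000  1.00  0.00           O",
    "END")
  writeLines(wat, f)
  p <- read_protein(f)
  expect_equal(nrow(p$atoms), 1)
})

test_that("alternate locations keep the highest occupancy, ties prefer A", {
  lines <- c(
    "ATOM      1  N  AGLY A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BGLY A   1       1.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AGLY A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   1       3.000   0.000   0.000  0.50  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  p <- read_protein(f)
  expect_equal(nrow(p$atoms), 2)
  # N: occupancy 0.6 wins (x = 1); CA: tie, altloc A wins (x = 2)
  expect_equal(sort(p$atoms$x), c(1, 2))
})
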