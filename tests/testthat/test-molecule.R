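test_that("SMILES parsing yields sanitized hydrogen-complete graphs", {
  b <- parse_molecule("c1ccccc1")
  expect_equal(sum(b$atoms$element == "C"), 6)
  expect_equal(sum(b$atoms$element == "H"), 6)
  expect_true(all(b$atoms$aromatic[b$atoms$element == "C"]))
  expect_equal(sum(b$bonds$aromatic), 6)
  expect_equal(sum(b$bonds$in_ring), 6)

  m <- parse_molecule("CC(=O)NC")
  expect_identical(canonical_smiles(m), canonical_smiles(parse_molecule("CNC(C)=O")))
  # the amide C-N bond exists and is acyclic
  expect_equal(count_rotatable_bonds(m), 0)
})

test_that("malformed and chemically impossible inputs fail loudly", {
  expect_error(parse_molecule("C1CC"), "could not convert")
  expect_error(parse_molecule("CC(C)(C)(C)C"), "valence")
  expect_error(parse_molecule("   "), "nzchar")
})

test_that("canonical serialization round-trips for diverse molecules", {
  smis <- c("c1ccccc1", "CCO", "CC(=O)NC", "c1ccc2ccccc2c1", "C1CCC2(CC1)CCCC2",
            "Oc1ccc(cc1)c1ccncc1", "C[NH3+]", "CC(=O)[O-]", "FC(F)(F)c1ccccc1",
            "c1cc[nH]c1", "O=C(Nc1ccccc1)c1ccccc1")
  for (s in smis) {
    m1 <- parse_molecule(s)
    c1 <- canonical_smiles(m1)
    m2 <- parse_molecule(c1)
    expect_identical(canonical_smiles(m2), c1, info = s)
    # round trip through an SDF block as well
    m3 <- parse_molecule(mol_to_molblock(m1, conformer = NULL), format = "sdf")
    expect_identical(canonical_smiles(m3), c1, info = s)
  }
})

test_that("formal charges survive the molblock round trip", {
  m <- parse_molecule("C[NH3+]")
  expect_equal(sum(m$atoms$charge), 1L)
  m2 <- parse_molecule(mol_to_molblock(m, NULL), format = "sdf")
  expect_equal(sum(m2$atoms$charge), 1L)
})

test_that("ring perception flags atoms and bonds correctly", {
  m <- parse_molecule("C1CCCCC1CC")  # ethylcyclohexane
  hv <- which(m$atoms$element != "H")
  expect_equal(sum(m$atoms$in_ring[hv]), 6)
  expect_equal(sum(m$bonds$in_ring), 6)
  sizes <- fraggrow:::ring_bond_sizes(m)
  expect_true(all(sizes == 6))
})

test_that("molecular weight matches known values", {
  expect_equal(molecular_weight(parse_molecule("c1ccccc1")), 78.11, tolerance = 1e-3)
  expect_equal(molecular_weight(parse_molecule("O")), 18.015, tolerance = 1e-3)
})
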