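test_that("toy complexes regenerate bitwise from seed and parameters", {
  a <- make_toy_complex("Oc1ccc(cc1)-c1ccncc1", seed = 21)
  b <- make_toy_complex("Oc1ccc(cc1)-c1ccncc1", seed = 21)
  expect_identical(a$protein$atoms, b$protein$atoms)
  expect_identical(a$ligand$conformers, b$ligand$conformers)
  c2 <- make_toy_complex("Oc1ccc(cc1)-c1ccncc1", seed = 22)
  expect_false(identical(a$protein$atoms, c2$protein$atoms))
})

test_that("the planted pose is clash-free and ideally satisfies hotspots", {
  toy <- fx_toy()
  pocket <- fx_pocket()
  hs <- fx_hotspots()
  xyz <- toy$ligand$conformers[[1]]
  hv <- which(toy$ligand$atoms$element != "H")
  expect_false(fraggrow:::has_hard_clash(xyz[hv, ], toy$ligand$atoms$element[hv],
                                         pocket, ratio = 0.7))
  ct <- fraggrow:::contact_table(ligand_features(toy$ligand, xyz), hs,
                                 default_energy_model())
  # every fragment engages at least one hotspot near-ideally
  for (fr in toy$fragments) {
    feats <- ligand_features(toy$ligand, xyz)
    frag_feats <- which(feats$atom %in% fr$src_atoms)
    g_best <- max(c(0, ct$g[ct$feature %in% frag_feats]))
    expect_gt(g_best, 0.9)
  }
})

test_that("an unusable fixture (no plantable feature) errors", {
  expect_error(make_toy_complex("C1CCCCC1", seed = 1), "unusable fixture")
})

test_that("fragment libraries contain the trues plus clean decoys", {
  toy <- fx_toy()
  lib <- make_fragment_library(toy$fragments, n_decoys = 10, seed = 3)
  expect_length(lib, 12)
  smis <- vapply(lib, function(f) canonical_smiles(f$mol), character(1))
  for (fr in toy$fragments) expect_true(canonical_smiles(fr$mol) %in% smis)
  # degenerate: no decoys
  lib0 <- make_fragment_library(toy$fragments, n_decoys = 0, seed = 3)
  expect_length(lib0, length(toy$fragments))
  # every decoy passes the core filter rules
  rules <- default_filter_rules()
  for (f in lib) expect_true(apply_mcf(f$mol, rules, "core")$passed)
  # deterministic shuffle
  lib2 <- make_fragment_library(toy$fragments, n_decoys = 10, seed = 3)
  expect_identical(vapply(lib2, `[[`, character(1), "id"),
                   vapply(lib, `[[`, character(1), "id"))
})

test_that("toy complexes serialize to PDB + SDF + SMILES library files", {
  toy <- fx_toy()
  dir <- withr::local_tempdir()
  paths <- write_toy_complex(toy, dir)
  expect_true(all(file.exists(unlist(paths))))
  p <- read_protein(paths$protein)
  expect_equal(nrow(p$atoms), nrow(toy$protein$atoms))
  lig <- parse_molecule(paste(readLines(paths$ligand), collapse = "\n"), "sdf")
  expect_identical(canonical_smiles(lig), toy$smiles)
  lib <- read_fragment_library(paths$library)
  expect_length(lib, length(toy$fragments))
})
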