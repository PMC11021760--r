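test_that("rotatable-bond counting follows the printed definition", {
  expect_equal(count_rotatable_bonds(parse_molecule("CC")), 0)        # terminal atoms
  expect_equal(count_rotatable_bonds(parse_molecule("CCCC")), 1)      # only C2-C3
  expect_equal(count_rotatable_bonds(parse_molecule("CC(=O)NC")), 0)  # amide excluded
  expect_equal(count_rotatable_bonds(parse_molecule("c1ccccc1-c1ccccc1")), 1)
  expect_equal(count_rotatable_bonds(parse_molecule("CCCCC")), 2)
  expect_equal(count_rotatable_bonds(parse_molecule("C1CCCCC1C1CCCCC1")), 1)
})

test_that("benign molecules pass, alerts are named with matched atoms", {
  rules <- default_filter_rules()
  expect_true(apply_mcf(parse_molecule("Cc1ccccc1"), rules)$passed)
  expect_true(apply_mcf(parse_molecule("Oc1ccc(cc1)c1ccncc1"), rules)$passed)

  res <- apply_mcf(parse_molecule("CC(=O)Cl"), rules)
  expect_false(res$passed)
  expect_true("acyl_halide" %in% res$violations$rule)
  expect_gt(length(res$violations$atoms[[which(res$violations$rule == "acyl_halide")]]), 0)

  res2 <- apply_mcf(parse_molecule("CCOOCC"), rules)
  expect_true("peroxide" %in% res2$violations$rule)
})

test_that("property bounds apply in enhanced mode only", {
  rules <- default_filter_rules()
  rules$properties$mw_max <- 300
  m310 <- parse_molecule("CCCCCCCCCCCCCCCCCCCCCC")  # docosane, ~310 Da
  expect_gt(molecular_weight(m310), 300)
  expect_true(apply_mcf(m310, rules, mode = "core")$passed)
  enh <- apply_mcf(m310, rules, mode = "enhanced")
  expect_false(enh$passed)
  expect_true("mw_max" %in% enh$violations$rule)
})

test_that("terminal-group alerts fire on peripheral substituents in enhanced mode", {
  rules <- default_filter_rules()
  # benzaldehyde: the aldehyde hangs off the ring periphery
  m <- parse_molecule("O=Cc1ccccc1")
  enh <- apply_mcf(m, rules, mode = "enhanced")
  expect_true("terminal_aldehyde" %in% enh$violations$rule)
})

test_that("filtering is idempotent and monotone in the alert list", {
  rules <- default_filter_rules()
  mols <- lapply(c("Cc1ccccc1", "CCO", "c1ccncc1", "CC(=O)Cl", "OO"), parse_molecule)
  pass1 <- vapply(mols, function(m) apply_mcf(m, rules)$passed, logical(1))
  pass2 <- vapply(mols[pass1], function(m) apply_mcf(m, rules)$passed, logical(1))
  expect_true(all(pass2))
  # adding an alert can only shrink the passing set
  rules2 <- rules
  rules2$alerts <- c(rules2$alerts,
                     list(list(name = "any_alcohol", smarts = "[OX2H1]",
                               severity = "reject", compiled = compile_smarts("[OX2H1]"))))
  pass3 <- vapply(mols, function(m) apply_mcf(m, rules2)$passed, logical(1))
  expect_true(all(pass3 <= pass1))
})

test_that("the SMARTS-subset matcher agrees with Open Babel match counts", {
  pats <- c("[CX3](=O)[F,Cl,Br]", "[OX2][OX2]", "[CX4]([OX2H1])[OX2H1]",
            "[CX3H1]=O", "N=N", "N=C=O", "[CX4]([OX2H1])[NX3]", "[OX2H1]",
            "c1ccccc1", "[NX3H2]")
  mols <- c("CC(=O)Cl", "CC(=O)Br", "OO", "CCOOC", "OC(O)C", "CC=O",
            "CN=NC", "CN=C=O", "Cc1ccccc1", "O=Cc1ccccc1", "NCC(O)N",
            "Oc1ccc(cc1)c1ccncc1", "NC(=O)c1ccccc1", "C1CCNC1")
  for (ms in mols) {
    m <- parse_molecule(ms)
    mb <- fraggrow:::mol_to_molblock(m, NULL)
    for (p in pats) {
      expect_equal(length(match_smarts(m, p)),
                   fraggrow:::ob_smarts_count(mb, p),
                   info = paste(ms, p))
    }
  }
})

test_that("uncompilable user patterns fail at load time, not mid-run", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alerts:",
               "  - {name: broken, smarts: '[[[', severity: reject}"), f)
  expect_error(load_filter_rules(f), "configuration error")
})
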