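test_that("attachment-point enumeration respects valence, amides and symmetry", {
  benz <- parse_molecule("c1ccccc1")
  expect_length(enumerate_attachment_points(benz), 1)  # one symmetry orbit
  expect_length(enumerate_attachment_points(benz, symmetry_reduce = FALSE), 6)
  neo <- parse_molecule("CC(C)(C)C")
  central <- which(vapply(seq_len(nrow(neo$atoms)), function(a) {
    neo$atoms$element[a] == "C" && sum(neo$atoms$element[fraggrow:::atom_neighbors(neo, a)] != "H") == 4
  }, logical(1)))
  expect_false(central %in% enumerate_attachment_points(neo, symmetry_reduce = FALSE))
  nma <- parse_molecule("CC(=O)NC")
  amide_n <- which(nma$atoms$element == "N")
  expect_false(amide_n %in% enumerate_attachment_points(nma, symmetry_reduce = FALSE))
  expect_true(amide_n %in%
                enumerate_attachment_points(nma, forbid = list(amide_n = FALSE),
                                            symmetry_reduce = FALSE))
  pyrrole <- parse_molecule("c1cc[nH]c1")
  n_idx <- which(pyrrole$atoms$element == "N")
  expect_true(n_idx %in% enumerate_attachment_points(pyrrole, symmetry_reduce = FALSE))
})

test_that("textbook linking identities hold by canonical-string equality", {
  benz <- parse_molecule("c1ccccc1")
  methyl <- fragment(parse_molecule("C"), id = "Me")
  phenyl <- fragment(benz, id = "Ph")
  expect_same_smiles(link_direct(benz, 1, methyl, 1), "Cc1ccccc1")
  expect_same_smiles(link_direct(benz, 1, phenyl, 1), "c1ccccc1-c1ccccc1")

  fused <- fuse_rings(benz, which(benz$bonds$in_ring)[1], phenyl,
                      which(benz$bonds$in_ring)[1])
  expect_gte(length(fused), 1)
  expect_same_smiles(fused[[1]], "c1ccc2ccccc2c1")

  cyhex <- parse_molecule("C1CCCCC1")
  cypent <- fragment(parse_molecule("C1CCCC1"), id = "cp")
  sp <- spiro_join(cyhex, fraggrow:::spiro_sites(cyhex)[1], cypent,
                   fraggrow:::spiro_sites(cypent$mol)[1])
  expect_same_smiles(sp, "C1CCC2(CC1)CCCC2")

  ch2 <- fragment_from_smiles("C", role = "linker")
  expect_same_smiles(link_via_linker(benz, 1, ch2, benz, 1), "c1ccccc1Cc1ccccc1")
})

test_that("aromatic/aliphatic fusion gives condensed systems (indane skeleton)", {
  benz <- parse_molecule("c1ccccc1")
  cp <- fragment(parse_molecule("C1CCCC1"), id = "cp")
  prods <- fuse_rings(benz, which(benz$bonds$in_ring)[1], cp,
                      which(cp$mol$bonds$in_ring)[1])
  expect_gte(length(prods), 1)
  expect_same_smiles(prods[[1]], "C1Cc2ccccc2C1")
})

test_that("illegal linking arguments raise contract errors", {
  benz <- parse_molecule("c1ccccc1")
  fb <- parse_molecule("Fc1ccccc1")
  methyl <- fragment(parse_molecule("C"), id = "Me")
  f_idx <- which(fb$atoms$element == "F")
  expect_error(link_direct(fb, f_idx, methyl, 1), "free valence")
  expect_error(fragment(parse_molecule("c1ccccc1"), role = "linker",
                        attachment = c(1, 2, 3)), "exactly 2")
  acyclic_bond <- which(!benz$bonds$in_ring)[1]
  expect_error(fuse_rings(benz, acyclic_bond, methyl, 1), "not a ring bond")
  cp <- fragment(parse_molecule("C1CCCC1"), id = "cp")
  expect_error(spiro_join(benz, 1, cp, fraggrow:::spiro_sites(cp$mol)[1]), "aromatic")
})

test_that("fusing a benzene bond across a pyridine nitrogen is rejected", {
  benz <- parse_molecule("c1ccccc1")
  pyr <- fragment(parse_molecule("c1ccncc1"), id = "py")
  n_idx <- which(pyr$mol$atoms$element == "N")
  k <- which(pyr$mol$bonds$in_ring &
               (pyr$mol$bonds$i == n_idx | pyr$mol$bonds$j == n_idx))[1]
  prods <- fuse_rings(benz, which(benz$bonds$in_ring)[1], pyr, k)
  expect_length(prods, 0)  # both mappings put N onto a C (element mismatch)
})

test_that("grow() matches the brute-force enumerator on small inputs", {
  parent_pool <- c("c1ccccc1", "Cc1ccncc1", "C1CCCCC1", "CCO")
  frag_pool <- c("C", "CC", "c1ccccc1", "C1CCCC1", "CO", "c1ccncc1")
  withr::with_seed(99, {
    for (rep in 1:6) {
      parents <- tibble::tibble(
        id = "p1",
        mol = list(parse_molecule(sample(parent_pool, 1))),
        iteration = 0L)
      lib <- lapply(sample(frag_pool, sample(2:3, 1)), function(s) {
        fragment(parse_molecule(s), id = s)
      })
      rules <- sample(c("direct", "fuse", "spiro"), sample(1:3, 1))
      got <- grow(parents, lib, rules = rules, symmetry_reduce = FALSE)
      expect_setequal(got$smiles, brute_force_products(parents, lib, rules))
    }
  })
})

test_that("grow() dedups identical products and records replayable lineage", {
  benz <- parse_molecule("c1ccccc1")
  parents <- tibble::tibble(id = "p1", mol = list(benz), iteration = 0L)
  lib <- list(fragment(parse_molecule("C"), id = "MeA"),
              fragment(parse_molecule("C"), id = "MeB"))
  kids <- grow(parents, lib, rules = "direct")
  expect_equal(nrow(kids), 1)  # duplicate fragment, deduplicated product
  expect_identical(kids$smiles[1], canonical_smiles(parse_molecule("Cc1ccccc1")))

  lib2 <- list(fragment(parse_molecule("c1ccncc1"), id = "py"),
               fragment(parse_molecule("C1CCCC1"), id = "cp"))
  kids2 <- grow(parents, lib2, rules = c("direct", "fuse", "spiro"))
  expect_gt(nrow(kids2), 1)
  for (q in seq_len(nrow(kids2))) {
    expect_identical(replay_lineage(kids2[q, ], parents, lib2), kids2$smiles[q])
  }
  # disabled rules produce nothing
  expect_equal(nrow(grow(parents, lib2, rules = character())), 0)
})

test_that("linker rule runs only in probe-probe context and replays", {
  benz <- parse_molecule("c1ccccc1")
  pyr <- parse_molecule("c1ccncc1")
  parents <- tibble::tibble(id = c("p1", "p2"), mol = list(benz, pyr), iteration = 0L)
  lib <- list(fragment_from_smiles("[*]C(=O)N[*]", role = "linker", id = "amide"))
  no_ctx <- grow(parents, lib, rules = "linker")
  expect_equal(nrow(no_ctx), 0)
  ctx <- tibble::tibble(id_a = "p1", id_b = "p2")
  kids <- grow(parents, lib, rules = "linker", pair_context = ctx)
  expect_gt(nrow(kids), 1)  # both orientations of the asymmetric linker
  for (q in seq_len(nrow(kids))) {
    expect_identical(replay_lineage(kids[q, ], parents, lib), kids$smiles[q])
  }
})

test_that("fragment libraries parse SMILES files with roles and dummies", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# comment",
               "c1ccccc1 Ph",
               "[*]CC[*] linker",
               "CO"), f)
  lib <- read_fragment_library(f)
  expect_length(lib, 3)
  expect_identical(lib[[1]]$id, "Ph")
  expect_identical(lib[[2]]$role, "linker")
  expect_length(lib[[2]]$attachment, 2)
})
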