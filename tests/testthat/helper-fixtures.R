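# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; no fixture files.

.fx <- new.env(parent = emptyenv())

fx_toy <- function() {
  if (is.null(.fx$toy)) .fx$toy <- make_toy_complex("Oc1ccc(cc1)-c1ccncc1", seed = 11)
  .fx$toy
}

fx_pocket <- function() {
  if (is.null(.fx$pocket)) {
    toy <- fx_toy()
    .fx$pocket <- extract_pocket(toy$protein, toy$ligand, cutoff = 5)
  }
  .fx$pocket
}

fx_hotspots <- function() {
  if (is.null(.fx$hotspots)) .fx$hotspots <- detect_hotspots(fx_pocket())
  .fx$hotspots
}

fx_mol <- function(smiles) parse_molecule(smiles)

# a pocket with no aromatic side chains (lysine + glycine shell only)
fx_polar_toy <- function() {
  if (is.null(.fx$polar)) .fx$polar <- make_toy_complex("OCCO", seed = 5, n_shell = 3)
  .fx$polar
}

# a toy whose ligand offers a donor but no acceptor (plants an aspartate)
fx_donor_toy <- function() {
  if (is.null(.fx$donor)) .fx$donor <- make_toy_complex("Nc1ccc(cc1)-c1ccncc1", seed = 5)
  .fx$donor
}

# a tiny generation run shared by pipeline tests (kept deliberately small)
fx_small_run <- function() {
  if (is.null(.fx$run)) {
    toy <- fx_toy()
    lib <- make_fragment_library(toy$fragments, n_decoys = 3, seed = 11)
    cfg <- generation_config(
      probes = toy$fragments, library = lib,
      rules = c("direct", "linker"), max_iterations = 1,
      k = 3, k_probes = 3, dock_top = 1, dock_restarts = 1,
      mw_ceiling = 300, seed = 11)
    .fx$run <- suppressWarnings(run_generation(toy$protein, toy$ligand, cfg))
  }
  .fx$run
}

expect_same_smiles <- function(mol, smiles) {
  expect_identical(canonical_smiles(mol),
                   fraggrow:::ob_smiles_to_cansmi(smiles))
}

# independent brute-force enumerator: nested loops over every rule with no
# symmetry reduction, used as the oracle for grow()
brute_force_products <- function(parents, library, rules) {
  out <- character()
  for (p in seq_len(nrow(parents))) {
    pmol <- parents$mol[[p]]
    sites <- enumerate_attachment_points(pmol, symmetry_reduce = FALSE)
    for (f in library) {
      if (f$role == "linker") next
      if ("direct" %in% rules) {
        frag_sites <- f$attachment
        for (ai in sites) for (bi in frag_sites) {
          child <- tryCatch(link_direct(pmol, ai, f, bi), error = function(e) NULL)
          if (!is.null(child)) out <- c(out, canonical_smiles(child))
        }
      }
      if ("fuse" %in% rules) {
        for (ka in which(pmol$bonds$in_ring)) for (kb in which(f$mol$bonds$in_ring)) {
          prods <- tryCatch(fuse_rings(pmol, ka, f, kb), error = function(e) list())
          out <- c(out, vapply(prods, canonical_smiles, character(1)))
        }
      }
      if ("spiro" %in% rules) {
        for (ia in fraggrow:::spiro_sites(pmol)) for (ib in fraggrow:::spiro_sites(f$mol)) {
          child <- tryCatch(spiro_join(pmol, ia, f, ib), error = function(e) NULL)
          if (!is.null(child)) out <- c(out, canonical_smiles(child))
        }
      }
    }
  }
  sort(unique(out))
}

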