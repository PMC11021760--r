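# Thin wrappers around ChemmineOB::convertFormat. Open Babel is the single
# source of truth for SMILES parsing, canonical SMILES, kekulization,
# aromaticity perception (via MOL2 bond types) and implicit-hydrogen filling.

ob_convert <- function(from, to, text, add_h = FALSE) {
  out <- if (add_h) {
    opts <- data.frame(names = "h", args = "", stringsAsFactors = FALSE)
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = text, options = opts))
  } else {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = text))
  }
  if (is.null(out) || !nzchar(trimws(out))) {
    stop("open babel could not convert input (", from, " -> ", to, "): ",
         substr(gsub("\n", " ", text), 1, 80), call. = FALSE)
  }
  out
}

# SMILES string -> kekulized V2000 molblock with explicit hydrogens.
ob_smiles_to_molblock <- function(smiles) {
  ob_convert("SMI", "SDF", paste0(smiles, "\n"), add_h = TRUE)
}

# Normalize any V2000 block: kekulize (order-4 aromatic bonds accepted on
# input), fill explicit hydrogens, keep heavy-atom order.
ob_normalize_molblock <- function(molblock) {
  ob_convert("SDF", "SDF", molblock, add_h = TRUE)
}

ob_molblock_to_cansmi <- function(molblock) {
  out <- ob_convert("SDF", "CAN", molblock)
  sub("[ \t\n].*$", "", out)
}

ob_smiles_to_cansmi <- function(smiles) {
  out <- ob_convert("SMI", "CAN", paste0(smiles, "\n"))
  sub("[ \t\n].*$", "", out)
}

# Aromatic bond perception: convert to MOL2 and read TRIPOS bond types.
# Returns a data.frame(i, j, aromatic).
ob_aromatic_bonds <- function(molblock) {
  mol2 <- ob_convert("SDF", "MOL2", molblock)
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  b0 <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)
  if (length(b0) == 0) return(data.frame(i = integer(), j = integer(), aromatic = logical()))
  rest <- lines[(b0[1] + 1):length(lines)]
  stop_at <- grep("^@<TRIPOS>", rest)
  if (length(stop_at)) rest <- rest[seq_len(stop_at[1] - 1)]
  rest <- rest[nzchar(trimws(rest))]
  if (!length(rest)) return(data.frame(i = integer(), j = integer(), aromatic = logical()))
  parts <- strsplit(trimws(rest), "[[:space:]]+")
  data.frame(
    i = vapply(parts, function(p) as.integer(p[2]), integer(1)),
    j = vapply(parts, function(p) as.integer(p[3]), integer(1)),
    aromatic = vapply(parts, function(p) identical(p[4], "ar"), logical(1))
  )
}

# Count SMARTS matches in a molecule given as a molblock.
ob_smarts_count <- function(molblock, smarts) {
  molrefs <- ChemmineOB::forEachMol("SDF", molblock, identity)
  n <- suppressWarnings(ChemmineOB::smartsSearch_OB(molrefs, smarts, uniqueMatches = TRUE))
  as.integer(n[[1]])
}
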