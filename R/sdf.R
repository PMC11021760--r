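# SDF (V2000) output of scored candidates, with score fields as data tags.

#' Write candidates to an SDF file
#'
#' One record per candidate with its docked pose embedded and all score
#' fields written as data tags (`binding_energy`, `pli_score`,
#' `shape_similarity`, `iteration`, `lineage`, plus `id` and `smiles`).
#'
#' @param cands candidate tibble; every row needs a `pose` matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(cands, path) {
  if (!nrow(cands)) {
    warning("writing empty SDF: no candidates")
    writeLines(character(0), path)
    return(invisible(path))
  }
  recs <- character(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    mol <- cands$mol[[i]]
    pose <- cands$pose[[i]]
    if (is.null(pose)) stop("candidate ", cands$id[i], " has no pose")
    mol$conformers <- list(pose)
    num <- function(x) formatC(x, format = "g", digits = 8)
    lineage <- paste0(cands$rule[i] %||% "probe", "(",
                      paste(cands$parents[[i]] %||% "", collapse = "+"),
                      if (!is.null(cands$fragment_id)) paste0("+", cands$fragment_id[i]) else "",
                      ")")
    data <- list(
      id = cands$id[i],
      smiles = cands$smiles[i],
      binding_energy = num(cands$binding_energy[i]),
      pli_score = num(cands$pli_score[i]),
      shape_similarity = num(cands$shape_similarity[i] %||% NA_real_),
      iteration = cands$iteration[i],
      lineage = lineage
    )
    recs[i] <- mol_to_molblock(mol, conformer = 1, title = cands$id[i], data = data)
  }
  writeLines(sub("\n$", "", paste(recs, collapse = "")), path)
  invisible(path)
}

#' Read a candidate SDF written by [write_sdf()]
#'
#' @param path SDF file path.
#' @return tibble with `id`, `smiles`, `mol` and `pose` list-columns plus the
#'   numeric score tags.
#' @export
read_candidates_sdf <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(text))) {
    return(tibble::tibble(id = character(), smiles = character(), mol = list(),
                          pose = list(), binding_energy = numeric(),
                          pli_score = numeric(), shape_similarity = numeric(),
                          iteration = integer()))
  }
  chunks <- strsplit(text, "\\$\\$\\$\\$\n?")[[1]]
  chunks <- chunks[nzchar(trimws(chunks))]
  rows <- lapply(chunks, function(ch) {
    mb <- paste0(ch, "\n$$$$\n")
    mol <- parse_molecule(mb, format = "sdf")
    tag <- function(nm) {
      m <- regmatches(ch, regexec(paste0(">  <", nm, ">\n([^\n]*)"), ch))[[1]]
      if (length(m) < 2) NA_character_ else m[2]
    }
    pose <- mol$conformers[[1]]
    tibble::tibble(
      id = tag("id"), smiles = canonical_smiles(mol),
      mol = list(mol), pose = list(pose),
      binding_energy = as.numeric(tag("binding_energy")),
      pli_score = as.numeric(tag("pli_score")),
      shape_similarity = suppressWarnings(as.numeric(tag("shape_similarity"))),
      iteration = as.integer(tag("iteration"))
    )
  })
  dplyr::bind_rows(rows)
}
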