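# Minimal SMARTS matcher with atom-index reporting.
#
# Open Babel counts SMARTS matches but does not expose which atoms matched,
# and filter diagnostics need the matched atoms. This matcher supports the
# subset of SMARTS used by the shipped medicinal-chemistry alerts: element
# symbols (aromatic lowercase), wildcards * / a / A, bracket atoms with
# element lists ([F,Cl,Br]), X<n> (total connections), H<n> (hydrogen
# count), R / !R ring membership, +/- charges, and bonds - = # : ~ plus the
# default single-or-aromatic bond. Patterns outside the subset fail to
# compile, and callers fall back to Open Babel match counting (indices then
# unavailable). Compiled patterns are cross-checked against Open Babel in
# the test suite.

.TWO_LETTER <- c("Cl", "Br")

smarts_tokenize_atom <- function(body) {
  # parse the inside of [...] into a constraint list
  cons <- list(elements = character(), aromatic = NA, exactH = NA_integer_,
               X = NA_integer_, charge = NA_integer_, ring = NA)
  s <- body
  while (nzchar(s)) {
    if (grepl("^!R", s)) { cons$ring <- FALSE; s <- substr(s, 3, nchar(s)); next }
    if (grepl("^R", s)) { cons$ring <- TRUE; s <- substr(s, 2, nchar(s)); next }
    if (grepl("^X[0-9]", s)) { cons$X <- as.integer(substr(s, 2, 2)); s <- substr(s, 3, nchar(s)); next }
    if (grepl("^H[0-9]", s)) { cons$exactH <- as.integer(substr(s, 2, 2)); s <- substr(s, 3, nchar(s)); next }
    if (grepl("^H", s)) { cons$exactH <- 1L; s <- substr(s, 2, nchar(s)); next }
    if (grepl("^\\+[0-9]", s)) { cons$charge <- as.integer(substr(s, 2, 2)); s <- substr(s, 3, nchar(s)); next }
    if (grepl("^-[0-9]", s)) { cons$charge <- -as.integer(substr(s, 2, 2)); s <- substr(s, 3, nchar(s)); next }
    if (grepl("^\\+", s)) { cons$charge <- 1L; s <- substr(s, 2, nchar(s)); next }
    if (grepl("^-", s)) { cons$charge <- -1L; s <- substr(s, 2, nchar(s)); next }
    if (grepl("^,", s) || grepl("^&", s) || grepl("^;", s)) { s <- substr(s, 2, nchar(s)); next }
    two <- substr(s, 1, 2)
    if (two %in% .TWO_LETTER) { cons$elements <- c(cons$elements, two); s <- substr(s, 3, nchar(s)); next }
    ch <- substr(s, 1, 1)
    if (ch %in% c("C", "N", "O", "S", "P", "F", "I", "B")) {
      cons$elements <- c(cons$elements, ch); s <- substr(s, 2, nchar(s)); next
    }
    if (ch %in% c("c", "n", "o", "s", "p")) {
      cons$elements <- c(cons$elements, toupper(ch)); cons$aromatic <- TRUE
      s <- substr(s, 2, nchar(s)); next
    }
    if (ch == "*") { s <- substr(s, 2, nchar(s)); next }
    if (ch == "a") { cons$aromatic <- TRUE; s <- substr(s, 2, nchar(s)); next }
    if (ch == "A") { cons$aromatic <- FALSE; s <- substr(s, 2, nchar(s)); next }
    stop("unsupported SMARTS primitive at '", s, "'")
  }
  cons
}

#' Compile a SMARTS pattern (supported subset)
#'
#' @param smarts pattern string.
#' @return an `fg_smarts` pattern object.
#' @export
compile_smarts <- function(smarts) {
  atoms <- list()
  bonds <- list()  # list(i, j, type): type in -,=,#,:,~,default
  open_rings <- list()
  stack <- integer()
  prev <- NA_integer_
  pend_bond <- "default"
  s <- smarts
  add_atom <- function(cons) {
    atoms[[length(atoms) + 1L]] <<- cons
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = idx, type = pend_bond)
    }
    pend_bond <<- "default"
    prev <<- idx
  }
  while (nzchar(s)) {
    ch <- substr(s, 1, 1)
    if (ch == "[") {
      close <- regexpr("]", s, fixed = TRUE)
      if (close < 0) stop("unterminated bracket atom in ", smarts)
      add_atom(smarts_tokenize_atom(substr(s, 2, close - 1)))
      s <- substr(s, close + 1, nchar(s)); next
    }
    if (ch == "(") { stack <- c(stack, prev); s <- substr(s, 2, nchar(s)); next }
    if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      s <- substr(s, 2, nchar(s)); next
    }
    if (ch %in% c("-", "=", "#", ":", "~")) { pend_bond <- ch; s <- substr(s, 2, nchar(s)); next }
    if (grepl("^[0-9]$", ch)) {
      key <- ch
      if (!is.null(open_rings[[key]])) {
        bonds[[length(bonds) + 1L]] <- list(i = open_rings[[key]]$atom, j = prev,
                                            type = open_rings[[key]]$bond)
        open_rings[[key]] <- NULL
      } else {
        open_rings[[key]] <- list(atom = prev, bond = pend_bond)
        pend_bond <- "default"
      }
      s <- substr(s, 2, nchar(s)); next
    }
    two <- substr(s, 1, 2)
    if (two %in% .TWO_LETTER) {
      add_atom(list(elements = two, aromatic = NA, exactH = NA_integer_,
                    X = NA_integer_, charge = NA_integer_, ring = NA))
      s <- substr(s, 3, nchar(s)); next
    }
    if (ch %in% c("C", "N", "O", "S", "P", "F", "I", "B")) {
      add_atom(list(elements = ch, aromatic = FALSE, exactH = NA_integer_,
                    X = NA_integer_, charge = NA_integer_, ring = NA))
      s <- substr(s, 2, nchar(s)); next
    }
    if (ch %in% c("c", "n", "o", "s", "p")) {
      add_atom(list(elements = toupper(ch), aromatic = TRUE, exactH = NA_integer_,
                    X = NA_integer_, charge = NA_integer_, ring = NA))
      s <- substr(s, 2, nchar(s)); next
    }
    if (ch == "*") {
      add_atom(list(elements = character(), aromatic = NA, exactH = NA_integer_,
                    X = NA_integer_, charge = NA_integer_, ring = NA))
      s <- substr(s, 2, nchar(s)); next
    }
    stop("unsupported SMARTS syntax at '", s, "' in ", smarts)
  }
  if (length(open_rings)) stop("unclosed ring bond in ", smarts)
  structure(list(atoms = atoms, bonds = bonds, smarts = smarts), class = "fg_smarts")
}

.atom_matches <- function(mol, a, cons) {
  el <- mol$atoms$element[a]
  if (el == "H") return(FALSE)
  if (length(cons$elements) && !el %in% cons$elements) return(FALSE)
  if (!is.na(cons$aromatic) && mol$atoms$aromatic[a] != cons$aromatic) return(FALSE)
  if (!is.na(cons$ring) && mol$atoms$in_ring[a] != cons$ring) return(FALSE)
  if (!is.na(cons$charge) && mol$atoms$charge[a] != cons$charge) return(FALSE)
  nh <- n_hydrogens(mol, a)
  if (!is.na(cons$exactH) && nh != cons$exactH) return(FALSE)
  if (!is.na(cons$X)) {
    deg <- length(atom_neighbors(mol, a))  # explicit-H model: total connections
    if (deg != cons$X) return(FALSE)
  }
  TRUE
}

.bond_matches <- function(mol, k, type) {
  b <- mol$bonds[k, ]
  switch(type,
    "default" = (b$order == 1L && !b$aromatic) || b$aromatic,
    "-" = b$order == 1L && !b$aromatic,
    "=" = b$order == 2L && !b$aromatic,
    "#" = b$order == 3L,
    ":" = isTRUE(b$aromatic),
    "~" = TRUE)
}

#' Match a compiled SMARTS pattern against a molecule
#'
#' @param mol a molecule.
#' @param pattern an `fg_smarts` (or pattern string).
#' @return list of integer vectors (atom indices, one per pattern atom);
#'   unique modulo atom-set equality.
#' @export
match_smarts <- function(mol, pattern) {
  if (is.character(pattern)) pattern <- compile_smarts(pattern)
  np <- length(pattern$atoms)
  if (np == 0) return(list())
  # adjacency of pattern
  padj <- vector("list", np)
  for (b in pattern$bonds) {
    padj[[b$i]] <- c(padj[[b$i]], list(list(j = b$j, type = b$type)))
    padj[[b$j]] <- c(padj[[b$j]], list(list(j = b$i, type = b$type)))
  }
  bond_idx <- function(i, j) {
    which((mol$bonds$i == min(i, j)) & (mol$bonds$j == max(i, j)))
  }
  results <- list()
  seen <- character()
  assign_vec <- rep(NA_integer_, np)
  # match pattern atoms in order 1..np (patterns are written connected)
  recurse <- function(pi) {
    if (pi > np) {
      key <- paste(sort(assign_vec), collapse = ",")
      if (!key %in% seen) {
        seen <<- c(seen, key)
        results[[length(results) + 1L]] <<- assign_vec
      }
      return(invisible())
    }
    cand <- heavy_atoms(mol)
    # restrict via already-assigned neighbors
    anchored <- FALSE
    for (e in padj[[pi]]) {
      if (!is.na(assign_vec[e$j])) {
        anchored <- TRUE
        cand <- intersect(cand, atom_neighbors(mol, assign_vec[e$j]))
      }
    }
    if (pi > 1 && !anchored) stop("disconnected SMARTS pattern unsupported: ", pattern$smarts)
    for (a in cand) {
      if (a %in% assign_vec) next
      if (!.atom_matches(mol, a, pattern$atoms[[pi]])) next
      ok <- TRUE
      for (e in padj[[pi]]) {
        if (is.na(assign_vec[e$j])) next
        k <- bond_idx(a, assign_vec[e$j])
        if (!length(k) || !.bond_matches(mol, k, e$type)) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_vec[pi] <<- a
      recurse(pi + 1L)
      assign_vec[pi] <<- NA_integer_
    }
    invisible()
  }
  recurse(1L)
  results
}
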