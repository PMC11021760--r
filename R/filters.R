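# Medicinal-chemistry filters: per-iteration core pass plus the enhanced
# final pass that also checks terminal functional groups and user property
# limits.

#' Load a medicinal-chemistry filter rule set
#'
#' Patterns are compiled at load time; an uncompilable user pattern is a
#' configuration error here, never a mid-run failure. Patterns outside the
#' supported SMARTS subset fall back to Open Babel matching (match counts
#' without atom indices).
#'
#' @param path YAML rule file; default is the rule set shipped with the
#'   package (`inst/extdata/mcf_rules.yaml`).
#' @return an `fg_filter_rules` object.
#' @export
load_filter_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mcf_rules.yaml", package = "fraggrow")
  }
  raw <- yaml::read_yaml(path)
  compile_list <- function(entries) {
    lapply(entries, function(e) {
      stopifnot(!is.null(e$name), !is.null(e$smarts))
      compiled <- tryCatch(compile_smarts(e$smarts), error = function(err) NULL)
      if (is.null(compiled)) {
        # must at least be a valid pattern for Open Babel
        probe <- tryCatch(
          ob_smarts_count(mol_to_molblock(parse_molecule("CC"), NULL), e$smarts),
          error = function(err) NULL)
        if (is.null(probe)) {
          stop("configuration error: SMARTS pattern for rule '", e$name,
               "' does not compile: ", e$smarts)
        }
      }
      list(name = e$name, smarts = e$smarts, severity = e$severity %||% "reject",
           compiled = compiled)
    })
  }
  structure(list(
    alerts = compile_list(raw$alerts %||% list()),
    terminal_alerts = compile_list(raw$terminal_alerts %||% list()),
    allowed_elements = raw$allowed_elements %||% c("C", "H", "N", "O", "S", "F", "Cl", "Br"),
    ring_size = raw$ring_size %||% list(min = 3, max = 8),
    properties = raw$properties %||% list()
  ), class = "fg_filter_rules")
}

default_filter_rules <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_filter_rules()
    cache
  }
})

# Match one alert: returns list of atom index vectors (possibly with length
# zero vectors when only Open Babel counting is available).
.match_alert <- function(mol, alert) {
  if (!is.null(alert$compiled)) {
    return(match_smarts(mol, alert$compiled))
  }
  n <- ob_smarts_count(mol_to_molblock(mol, NULL), alert$smarts)
  if (n > 0) rep(list(integer()), n) else list()
}

# Acyclic peripheral components: maximal connected sets of non-ring heavy
# atoms that touch at most one ring system (terminal substituents). Used by
# the enhanced pass to focus on terminal functional groups.
terminal_components <- function(mol) {
  hv <- heavy_atoms(mol)
  acyc <- hv[!mol$atoms$in_ring[hv]]
  if (!length(acyc)) return(list())
  b <- mol$bonds
  keep <- b$i %in% acyc & b$j %in% acyc
  g <- igraph::make_empty_graph(length(acyc), directed = FALSE)
  if (any(keep)) {
    el <- cbind(match(b$i[keep], acyc), match(b$j[keep], acyc))
    g <- igraph::add_edges(g, t(el))
  }
  comp <- igraph::components(g)$membership
  out <- list()
  for (cid in unique(comp)) {
    members <- acyc[comp == cid]
    # ring atoms this component is attached to
    ring_nb <- unique(unlist(lapply(members, function(a) {
      nb <- atom_neighbors(mol, a)
      nb[mol$atoms$in_ring[nb]]
    })))
    if (length(ring_nb) <= 1) {
      out[[length(out) + 1L]] <- sort(members)
    }
  }
  out
}

#' Apply medicinal-chemistry filters to a molecule
#'
#' Core mode evaluates every structural alert, the element whitelist and the
#' ring-size bounds. Enhanced mode additionally evaluates terminal-group
#' alerts against acyclic peripheral substituents and the user property
#' bounds (molecular weight, heavy atoms, rotatable bonds, ring count).
#' All violations are reported, not just the first.
#'
#' @param mol a sanitized molecule.
#' @param rules an `fg_filter_rules` (default: shipped rule set).
#' @param mode `"core"` or `"enhanced"`.
#' @return an `fg_filter_result`: list with `passed` (logical) and
#'   `violations` (tibble: `rule`, `class`, `n_matches`, `atoms` list-column).
#' @export
apply_mcf <- function(mol, rules = default_filter_rules(), mode = c("core", "enhanced")) {
  mode <- match.arg(mode)
  viol <- list()
  note <- function(rule, class, matches) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(
      rule = rule, class = class, n_matches = length(matches),
      atoms = list(sort(unique(unlist(matches)))))
  }

  for (al in rules$alerts) {
    m <- .match_alert(mol, al)
    if (length(m)) note(al$name, "alert", m)
  }

  bad_el <- setdiff(unique(mol$atoms$element), rules$allowed_elements)
  if (length(bad_el)) {
    note(paste0("element:", paste(bad_el, collapse = ",")), "element",
         list(which(mol$atoms$element %in% bad_el)))
  }

  sizes <- ring_bond_sizes(mol)
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) && (min(sizes) < rules$ring_size$min || max(sizes) > rules$ring_size$max)) {
    note("ring_size", "ring", list(integer()))
  }

  if (mode == "enhanced") {
    comps <- terminal_components(mol)
    for (al in rules$terminal_alerts) {
      m <- .match_alert(mol, al)
      m <- Filter(function(mm) {
        if (!length(mm)) return(FALSE)  # unlocated matches cannot be confirmed terminal
        hvm <- mm[mol$atoms$element[mm] != "H"]
        any(vapply(comps, function(cc) all(hvm %in% cc), logical(1)))
      }, m)
      if (length(m)) note(al$name, "terminal_alert", m)
    }
    pr <- rules$properties
    if (!is.null(pr$mw_max) && molecular_weight(mol) > pr$mw_max) {
      note("mw_max", "property", list(integer()))
    }
    if (!is.null(pr$heavy_atoms_max) && length(heavy_atoms(mol)) > pr$heavy_atoms_max) {
      note("heavy_atoms_max", "property", list(integer()))
    }
    if (!is.null(pr$rotatable_bonds_max) &&
        count_rotatable_bonds(mol) > pr$rotatable_bonds_max) {
      note("rotatable_bonds_max", "property", list(integer()))
    }
    if (!is.null(pr$ring_count_max) &&
        length(smallest_rings(mol)) > pr$ring_count_max) {
      note("ring_count_max", "property", list(integer()))
    }
  }

  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(rule = character(), class = character(),
                   n_matches = integer(), atoms = list())
  structure(list(passed = nrow(violations) == 0, violations = violations),
            class = "fg_filter_result")
}

#' @export
print.fg_filter_result <- function(x, ...) {
  if (x$passed) cat("<filter: passed>\n")
  else {
    cat("<filter: FAILED>\n")
    print(x$violations[, c("rule", "class", "n_matches")])
  }
  invisible(x)
}

#' Count rotatable bonds
#'
#' A rotatable bond is any single non-ring bond between two non-terminal
#' heavy atoms, excluding amide C-N bonds.
#'
#' @param mol a molecule.
#' @return integer count.
#' @examples
#' count_rotatable_bonds(parse_molecule("CCCC"))  # 1
#' @export
count_rotatable_bonds <- function(mol) {
  b <- mol$bonds
  hv <- heavy_atoms(mol)
  heavy_degree <- vapply(seq_len(n_atoms(mol)), function(a) {
    nb <- atom_neighbors(mol, a)
    sum(mol$atoms$element[nb] != "H")
  }, integer(1))
  is_amide_cn <- function(i, j) {
    # C-N single bond where the C bears a double-bonded O
    for (swap in list(c(i, j), c(j, i))) {
      c0 <- swap[1]; n0 <- swap[2]
      if (mol$atoms$element[c0] == "C" && mol$atoms$element[n0] == "N") {
        k <- which((b$i == c0 | b$j == c0) & b$order == 2L)
        if (any(mol$atoms$element[setdiff(c(b$i[k], b$j[k]), c0)] == "O")) return(TRUE)
      }
    }
    FALSE
  }
  count <- 0L
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1L || b$aromatic[k] || b$in_ring[k]) next
    i <- b$i[k]; j <- b$j[k]
    if (mol$atoms$element[i] == "H" || mol$atoms$element[j] == "H") next
    if (heavy_degree[i] < 2 || heavy_degree[j] < 2) next  # terminal atom
    if (is_amide_cn(i, j)) next
    count <- count + 1L
  }
  count
}
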