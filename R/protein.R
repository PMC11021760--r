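#' Read a protein structure from a PDB file
#'
#' Parsing is delegated to [bio3d::read.pdb()]. ATOM records become the
#' protein atom table; waters are dropped; alternate locations are resolved
#' by keeping the highest-occupancy altloc (ties go to altloc 'A'); HETATM
#' records (minus waters) are returned separately as candidate reference
#' ligands.
#'
#' @param path path to a PDB file.
#' @param keep_hetatm return HETATM records in the `hetatm` element.
#' @return an `fg_protein`: list with `atoms` (tibble: `element`, `resname`,
#'   `resno`, `chain`, `insert`, `atom_name`, `x`, `y`, `z`, `reskey`) and
#'   `hetatm` (same shape, possibly empty). `reskey` is
#'   `"<chain>:<resno><insert>"` and is the residue identity used everywhere
#'   downstream.
#' @export
read_protein <- function(path, keep_hetatm = TRUE) {
  stopifnot(file.exists(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
  at <- pdb$atom
  if (!any(at$type == "ATOM")) stop("format error: no ATOM records in ", path)
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  # altloc resolution: keep the highest-occupancy altloc per atom identity
  at$alt[is.na(at$alt)] <- ""
  if (any(nzchar(at$alt))) {
    ident <- paste(at$type, at$chain, at$resno, at$insert, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), ident), function(idx) {
      if (length(idx) == 1) return(idx)
      occ <- at$o[idx]; occ[is.na(occ)] <- 1
      best <- idx[occ == max(occ)]
      if (length(best) > 1) {
        alt_a <- best[at$alt[best] %in% c("A", "")]
        best <- if (length(alt_a)) alt_a[1] else best[1]
      }
      best
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    elem <- substr(trimws(at$elety), 1, 1)
  }
  elem <- trimws(elem)
  elem[elem == ""] <- substr(trimws(at$elety[elem == ""]), 1, 1)
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 2)))
  elem <- sub(" $", "", elem)
  ins <- at$insert; ins[is.na(ins)] <- ""
  tab <- tibble::tibble(
    type = at$type,
    element = elem,
    resname = at$resid,
    resno = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    insert = ins,
    atom_name = trimws(at$elety),
    x = at$x, y = at$y, z = at$z
  )
  tab$reskey <- paste0(tab$chain, ":", tab$resno, tab$insert)
  if (any(!is.finite(c(tab$x, tab$y, tab$z)))) stop("non-finite coordinates in ", path)
  structure(
    list(
      atoms = tab[tab$type == "ATOM", setdiff(names(tab), "type")],
      hetatm = if (keep_hetatm) tab[tab$type == "HETATM", setdiff(names(tab), "type")]
               else tab[0, setdiff(names(tab), "type")],
      source = path
    ),
    class = "fg_protein"
  )
}

#' @export
print.fg_protein <- function(x, ...) {
  cat(sprintf("<protein: %d atoms, %d residues, %d hetatm>\n",
              nrow(x$atoms), length(unique(x$atoms$reskey)), nrow(x$hetatm)))
  invisible(x)
}

protein_xyz <- function(protein, idx = NULL) {
  a <- protein$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  cbind(a$x, a$y, a$z)
}

# Apply a rigid transform to every coordinate in the structure (used by
# invariance tests and fixture construction).
transform_protein <- function(protein, R, t) {
  for (nm in c("atoms", "hetatm")) {
    if (!nrow(protein[[nm]])) next
    xyz <- apply_rigid(cbind(protein[[nm]]$x, protein[[nm]]$y, protein[[nm]]$z), R, t)
    protein[[nm]]$x <- xyz[, 1]; protein[[nm]]$y <- xyz[, 2]; protein[[nm]]$z <- xyz[, 3]
  }
  protein
}

#' Write a protein structure to a PDB file
#'
#' Thin wrapper over [bio3d::write.pdb()]; used by the fixture generator and
#' the hotspot dump.
#'
#' @param protein an `fg_protein`.
#' @param path output file path.
#' @export
write_protein <- function(protein, path) {
  a <- protein$atoms
  n <- nrow(a)
  bio3d::write.pdb(
    file = path,
    type = rep("ATOM", n),
    eleno = seq_len(n),
    elety = a$atom_name,
    resid = a$resname,
    chain = a$chain,
    resno = a$resno,
    insert = ifelse(nzchar(a$insert), a$insert, ""),
    xyz = as.vector(t(cbind(a$x, a$y, a$z))),
    o = rep(1, n), b = rep(0, n),
    elesy = a$element
  )
  invisible(path)
}
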