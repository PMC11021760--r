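#' Molecular data model
#'
#' A `fg_mol` is the hydrogen-complete molecular graph used throughout the
#' package. It stores an atom table, a bond table and zero or more conformer
#' coordinate sets (Cartesian angstroms). Bond orders are kept kekulized
#' (1, 2, 3) with a separate aromatic flag perceived by Open Babel, so the
#' same graph can be written back to V2000 either kekulized or with aromatic
#' (order 4) bonds.
#'
#' Fields:
#' * `atoms`: tibble with `element`, `charge`, `aromatic`, `in_ring`,
#'   `provenance` (free-form tag: `"new"` or `"<parent_id>:<parent_atom>"`).
#' * `bonds`: tibble with `i`, `j` (1-based atom indices, `i < j`), `order`,
#'   `aromatic`, `in_ring`.
#' * `conformers`: list of `n_atoms x 3` coordinate matrices.
#'
#' @name molecule
NULL

new_molecule <- function(atoms, bonds, conformers = list()) {
  n <- nrow(atoms)
  adj <- rep(list(integer()), n)
  if (nrow(bonds)) {
    sp <- split(c(bonds$j, bonds$i), c(bonds$i, bonds$j))
    adj[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  nH <- vapply(adj, function(v) sum(atoms$element[v] == "H"), integer(1))
  structure(
    list(atoms = atoms, bonds = bonds, conformers = conformers,
         adj = adj, nH = nH),
    class = "fg_mol"
  )
}

#' @export
print.fg_mol <- function(x, ...) {
  nh <- sum(x$atoms$element != "H")
  cat(sprintf(
    "<molecule: %d atoms (%d heavy), %d bonds, %d conformer(s)>\n  %s\n",
    nrow(x$atoms), nh, nrow(x$bonds), length(x$conformers),
    tryCatch(canonical_smiles(x), error = function(e) "<unserializable>")
  ))
  invisible(x)
}

is_molecule <- function(x) inherits(x, "fg_mol")

n_atoms <- function(mol) nrow(mol$atoms)

heavy_atoms <- function(mol) which(mol$atoms$element != "H")

#' Molecular weight in daltons
#' @param mol a molecule.
#' @return numeric scalar (Da), hydrogens included.
#' @export
molecular_weight <- function(mol) {
  sum(atomic_mass(mol$atoms$element))
}

# Neighbor list helper: integer indices of atoms bonded to `idx`.
atom_neighbors <- function(mol, idx) {
  if (!is.null(mol$adj)) return(mol$adj[[idx]])
  b <- mol$bonds
  c(b$j[b$i == idx], b$i[b$j == idx])
}

# Number of hydrogens attached to atom idx (explicit-H model).
n_hydrogens <- function(mol, idx) {
  if (!is.null(mol$nH)) return(mol$nH[idx])
  nb <- atom_neighbors(mol, idx)
  sum(mol$atoms$element[nb] == "H")
}

# Sum of bond orders at an atom (aromatic bonds count by kekulized order).
bond_order_sum <- function(mol, idx) {
  b <- mol$bonds
  sum(b$order[b$i == idx | b$j == idx])
}

# Vectorized bond-order sums for all atoms.
bond_order_sums <- function(mol) {
  n <- n_atoms(mol)
  out <- numeric(n)
  if (nrow(mol$bonds)) {
    s <- rowsum(c(mol$bonds$order, mol$bonds$order),
                c(mol$bonds$i, mol$bonds$j))
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Check chemical valences
#'
#' Verifies that every atom's total bond order is legal for its element and
#' formal charge (e.g. C 4, neutral N 3, N+ 4, O 2, O- 1, S 2/4/6).
#'
#' @param mol a molecule.
#' @return `TRUE`, or a character vector describing each violation.
#' @export
check_valences <- function(mol) {
  bad <- character()
  vsum <- bond_order_sums(mol)
  for (a in seq_len(n_atoms(mol))) {
    el <- mol$atoms$element[a]
    chg <- mol$atoms$charge[a]
    allowed <- .ALLOWED_VALENCE[[el]]
    if (is.null(allowed)) next  # unknown element: not judged here
    # charge adjustment: +1 raises allowed valence for N/O/S/P/C, -1 lowers it
    if (el %in% c("N", "O", "S", "P", "C")) allowed <- allowed + chg
    v <- vsum[a]
    if (!v %in% allowed && !(v == 0 && n_atoms(mol) == 1)) {
      bad <- c(bad, sprintf("atom %d (%s, charge %+d): valence %d not in {%s}",
                            a, el, chg, v, paste(allowed, collapse = ",")))
    }
  }
  if (length(bad)) bad else TRUE
}

# ---------------------------------------------------------------------------
# V2000 molblock I/O

# Write a molblock from a molecule. `conformer = NULL` writes zero coordinates
# (graph-only). `aromatic_as_4` writes perceived-aromatic bonds as order 4 so
# Open Babel re-kekulizes on read (used after graph surgery).
mol_to_molblock <- function(mol, conformer = 1L, title = "", aromatic_as_4 = FALSE,
                            data = NULL) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  xyz <- matrix(0, n, 3)
  dim_tag <- "2D"
  if (!is.null(conformer) && length(mol$conformers) >= conformer) {
    xyz <- mol$conformers[[conformer]]
    dim_tag <- "3D"
  }
  chgcode <- c(`3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L, `-3` = 7L)
  cc <- chgcode[as.character(mol$atoms$charge)]
  cc[is.na(cc)] <- 0L
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                        xyz[, 1], xyz[, 2], xyz[, 3], mol$atoms$element, cc)
  bond_lines <- character(0)
  if (nb > 0) {
    ord <- mol$bonds$order
    if (aromatic_as_4) ord[mol$bonds$aromatic] <- 4L
    bond_lines <- sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i, mol$bonds$j, ord)
  }
  lines <- c(
    title,
    sprintf(" fraggrow          %s", dim_tag),
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    atom_lines,
    bond_lines
  )
  charged <- which(mol$atoms$charge != 0L)
  if (length(charged)) {
    for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
      lines <- c(lines, paste0(sprintf("M  CHG%3d", length(grp)),
                               paste(sprintf("%4d%4d", grp, mol$atoms$charge[grp]), collapse = "")))
    }
  }
  lines <- c(lines, "M  END")
  if (!is.null(data) && length(data)) {
    for (nm in names(data)) {
      lines <- c(lines, sprintf(">  <%s>", nm), as.character(data[[nm]]), "")
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n$$$$\n")
}

# Parse the first record of a V2000 molblock (fixed-width per the CTfile
# spec). A minimal reader is used on this hot path — every grown candidate
# passes through it — with M CHG lines honored over the legacy charge
# column.
parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("not a molblock")
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || length(lines) < 4 + na + nb) {
    stop("malformed molblock counts line: ", counts)
  }
  al <- lines[4 + seq_len(na)]
  xyz <- cbind(as.numeric(substr(al, 1, 10)),
               as.numeric(substr(al, 11, 20)),
               as.numeric(substr(al, 21, 30)))
  elements <- trimws(substr(al, 32, 34))
  code <- suppressWarnings(as.integer(substr(al, 37, 39)))
  code[is.na(code)] <- 0L
  charge <- integer(na)
  charge[code %in% 1:3] <- 4L - code[code %in% 1:3]
  charge[code %in% 5:7] <- 4L - code[code %in% 5:7]
  # M CHG lines override the legacy column
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    vals <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "[[:space:]]+")[[1]])
    nn <- vals[1]
    if (length(vals) >= 1 + 2 * nn) {
      idx <- vals[seq(2, by = 2, length.out = nn)]
      charge[idx] <- vals[seq(3, by = 2, length.out = nn)]
    }
  }
  atoms <- tibble::tibble(
    element = elements, charge = charge,
    aromatic = FALSE, in_ring = FALSE, provenance = "new"
  )
  if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    bi <- as.integer(substr(bl, 1, 3)); bj <- as.integer(substr(bl, 4, 6))
    bonds <- tibble::tibble(
      i = pmin(bi, bj), j = pmax(bi, bj),
      order = as.integer(substr(bl, 7, 9)),
      aromatic = FALSE, in_ring = FALSE
    )
  } else {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = integer(),
                            aromatic = logical(), in_ring = logical())
  }
  list(atoms = atoms, bonds = bonds, xyz = xyz)
}

# Ring perception on the molecular graph: a bond is in a ring iff it is not a
# bridge; an atom is in a ring iff it has >= 2 ring bonds.
perceive_rings <- function(atoms, bonds) {
  if (nrow(bonds) == 0) {
    return(list(atom_in_ring = rep(FALSE, nrow(atoms)), bond_in_ring = logical(0)))
  }
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]), directed = FALSE)
  if (igraph::vcount(g) < nrow(atoms)) {
    g <- igraph::add_vertices(g, nrow(atoms) - igraph::vcount(g))
  }
  br <- igraph::bridges(g)
  bond_in_ring <- !seq_len(nrow(bonds)) %in% as.integer(br)
  cnt <- integer(nrow(atoms))
  for (k in which(bond_in_ring)) {
    cnt[bonds$i[k]] <- cnt[bonds$i[k]] + 1L
    cnt[bonds$j[k]] <- cnt[bonds$j[k]] + 1L
  }
  list(atom_in_ring = cnt >= 2L, bond_in_ring = bond_in_ring)
}

# Size of the smallest ring containing bond k, or NA if acyclic bond.
smallest_ring_size <- function(mol, k) {
  b <- mol$bonds
  if (!b$in_ring[k]) return(NA_integer_)
  g <- igraph::graph_from_edgelist(as.matrix(b[, c("i", "j")]), directed = FALSE)
  if (igraph::vcount(g) < n_atoms(mol)) {
    g <- igraph::add_vertices(g, n_atoms(mol) - igraph::vcount(g))
  }
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(b$i[k], b$j[k])))
  d <- igraph::distances(g2, v = b$i[k], to = b$j[k])[1, 1]
  if (!is.finite(d)) return(NA_integer_)
  as.integer(d + 1)
}

# All smallest-ring sizes present in the molecule (one entry per ring bond).
ring_bond_sizes <- function(mol) {
  ks <- which(mol$bonds$in_ring)
  vapply(ks, function(k) smallest_ring_size(mol, k), integer(1))
}

# Build a molecule from a normalized (kekulized, H-complete) molblock,
# perceiving aromaticity and rings. Internal workhorse behind parse_molecule()
# and sanitize_molecule().
molecule_from_normalized_molblock <- function(molblock, keep_coords = TRUE) {
  p <- parse_molblock(molblock)
  ar <- ob_aromatic_bonds(molblock)
  bonds <- p$bonds
  if (nrow(bonds) && nrow(ar)) {
    key <- paste(pmin(ar$i, ar$j), pmax(ar$i, ar$j))
    bkey <- paste(bonds$i, bonds$j)
    bonds$aromatic <- bkey %in% key[ar$aromatic]
  }
  atoms <- p$atoms
  if (nrow(bonds)) {
    arom_atoms <- unique(c(bonds$i[bonds$aromatic], bonds$j[bonds$aromatic]))
    atoms$aromatic[arom_atoms] <- TRUE
  }
  rings <- perceive_rings(atoms, bonds)
  atoms$in_ring <- rings$atom_in_ring
  bonds$in_ring <- rings$bond_in_ring
  confs <- list()
  if (keep_coords && any(abs(p$xyz) > 1e-8)) confs <- list(unname(p$xyz))
  new_molecule(atoms, bonds, confs)
}

#' Parse a molecule from SMILES or an SDF block
#'
#' Parsing, kekulization, aromaticity perception and implicit-hydrogen
#' materialization are delegated to Open Babel; the result is a sanitized,
#' hydrogen-complete molecular graph. SDF input retains its coordinates
#' (hydrogens added by Open Babel are placed geometrically when the input has
#' 3D coordinates).
#'
#' @param text a SMILES string or the text of one SDF record.
#' @param format `"smiles"` or `"sdf"`.
#' @return a molecule (`fg_mol`).
#' @examples
#' benzene <- parse_molecule("c1ccccc1")
#' canonical_smiles(benzene)
#' @export
parse_molecule <- function(text, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  stopifnot(is.character(text), length(text) == 1, nzchar(trimws(text)))
  molblock <- switch(format,
    smiles = ob_smiles_to_molblock(text),
    sdf = ob_normalize_molblock(text)
  )
  mol <- molecule_from_normalized_molblock(molblock)
  v <- check_valences(mol)
  if (!isTRUE(v)) {
    stop("chemistry error in '", substr(text, 1, 60), "': ",
         paste(v, collapse = "; "), call. = FALSE)
  }
  mol
}

#' Canonical SMILES of a molecule
#'
#' The canonical string (Open Babel canonical SMILES) is the deduplication
#' key for generated structures and the round-trip identity used in tests.
#'
#' @param mol a molecule.
#' @return character scalar.
#' @export
canonical_smiles <- function(mol) {
  ob_molblock_to_cansmi(mol_to_molblock(mol, conformer = NULL))
}

# Re-perceive a molecule after graph surgery: write heavy-atom graph with
# aromatic bonds as order 4, let Open Babel kekulize and re-add hydrogens.
# Returns NULL (rejection) when the product cannot be sanitized. Heavy-atom
# order (and therefore provenance) is preserved.
sanitize_molecule <- function(atoms, bonds) {
  tmp <- new_molecule(atoms, bonds)
  mb <- mol_to_molblock(tmp, conformer = NULL, aromatic_as_4 = TRUE)
  norm <- tryCatch(ob_normalize_molblock(mb), error = function(e) NULL)
  if (is.null(norm)) return(NULL)
  mol <- tryCatch(molecule_from_normalized_molblock(norm, keep_coords = FALSE),
                  error = function(e) NULL)
  if (is.null(mol)) return(NULL)
  n_heavy_in <- sum(atoms$element != "H")
  heavy_out <- heavy_atoms(mol)
  if (length(heavy_out) != n_heavy_in) return(NULL)  # order/atom-count mismatch
  if (!identical(mol$atoms$element[heavy_out], atoms$element[atoms$element != "H"])) {
    return(NULL)
  }
  mol$atoms$provenance[heavy_out] <- atoms$provenance[atoms$element != "H"]
  if (!isTRUE(check_valences(mol))) return(NULL)
  mol
}

# Heavy-atom molecular graph as igraph, vertices colored for automorphism
# work: color = element | charge | aromatic | hydrogen count.
heavy_graph <- function(mol) {
  hv <- heavy_atoms(mol)
  remap <- match(seq_len(n_atoms(mol)), hv)
  b <- mol$bonds
  keep <- b$i %in% hv & b$j %in% hv
  el <- cbind(remap[b$i[keep]], remap[b$j[keep]])
  g <- igraph::make_empty_graph(n = length(hv), directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  nh <- vapply(hv, function(a) n_hydrogens(mol, a), integer(1))
  lab <- paste(mol$atoms$element[hv], mol$atoms$charge[hv],
               mol$atoms$aromatic[hv], nh, sep = "|")
  igraph::V(g)$color_label <- lab
  igraph::E(g)$order <- ifelse(b$aromatic[keep], 4L, b$order[keep])
  g
}
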