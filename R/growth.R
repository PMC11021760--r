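# Graph-level linking rules: direct single bond, linker-mediated bridge,
# ring fusion and spiro junction. All operations work on hydrogen-complete
# molecules, do the surgery on the heavy-atom graph, and re-perceive the
# product (kekulization, aromaticity, hydrogens) via sanitize_molecule();
# a product that cannot be sanitized is a rejection (NULL), not an error.

#' Build a fragment
#'
#' @param mol a molecule (hydrogen-complete).
#' @param attachment heavy-atom indices usable as attachment points; `NULL`
#'   derives them with [enumerate_attachment_points()].
#' @param role `"probe"`, `"building_block"` or `"linker"` (linkers must have
#'   exactly 2 attachment points).
#' @param id identifier used in lineage records.
#' @return an `fg_fragment`.
#' @export
fragment <- function(mol, attachment = NULL, role = "building_block", id = NULL) {
  stopifnot(is_molecule(mol), role %in% c("probe", "building_block", "linker"))
  if (is.null(attachment)) attachment <- enumerate_attachment_points(mol)
  attachment <- as.integer(attachment)
  for (a in attachment) {
    if (n_hydrogens(mol, a) < 1) {
      stop("attachment atom ", a, " has no hydrogen / free valence")
    }
  }
  if (role == "linker" && length(attachment) == 1 && n_hydrogens(mol, attachment) >= 2) {
    attachment <- rep(attachment, 2)  # single-atom linker (e.g. methylene)
  }
  if (role == "linker" && length(attachment) != 2) {
    stop("linker fragment must have exactly 2 attachment points, got ", length(attachment))
  }
  structure(list(mol = mol, attachment = attachment, role = role,
                 id = id %||% canonical_smiles(mol)),
            class = "fg_fragment")
}

#' @export
print.fg_fragment <- function(x, ...) {
  cat(sprintf("<fragment %s [%s]: sites %s>\n", x$id, x$role,
              paste(x$attachment, collapse = ",")))
  invisible(x)
}

#' Enumerate attachment points of a molecule
#'
#' Heavy atoms carrying at least one hydrogen (free valence), minus atoms
#' whose substitution is forbidden (amide N by default), optionally reduced
#' to one representative per symmetry orbit of the molecular graph.
#'
#' @param mol a molecule.
#' @param forbid list of forbidden-site rules; currently `amide_n`.
#' @param symmetry_reduce keep one site per automorphism orbit.
#' @return integer vector of atom indices.
#' @export
enumerate_attachment_points <- function(mol, forbid = list(amide_n = TRUE),
                                        symmetry_reduce = TRUE) {
  hv <- heavy_atoms(mol)
  sites <- integer()
  for (a in hv) {
    if (n_hydrogens(mol, a) < 1) next
    if (isTRUE(forbid$amide_n) && mol$atoms$element[a] == "N") {
      nb <- atom_neighbors(mol, a)
      nb <- nb[mol$atoms$element[nb] == "C"]
      is_amide <- any(vapply(nb, function(c0) {
        k <- which((mol$bonds$i == c0 | mol$bonds$j == c0) & mol$bonds$order == 2L)
        any(mol$atoms$element[setdiff(c(mol$bonds$i[k], mol$bonds$j[k]), c0)] == "O")
      }, logical(1)))
      if (is_amide) next
    }
    sites <- c(sites, a)
  }
  if (symmetry_reduce && length(sites) > 1) {
    orb <- heavy_orbits(mol)
    pos <- match(sites, hv)
    sites <- sites[!duplicated(orb[pos])]
  }
  sites
}

# Heavy-atom-only copy of a molecule: atoms/bonds renumbered, mapping kept.
strip_hydrogens <- function(mol) {
  hv <- heavy_atoms(mol)
  remap <- match(seq_len(n_atoms(mol)), hv)
  b <- mol$bonds
  keep <- b$i %in% hv & b$j %in% hv
  atoms <- mol$atoms[hv, , drop = FALSE]
  bonds <- b[keep, , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  list(atoms = atoms, bonds = bonds, map = hv)  # map[k] = original index of heavy atom k
}

# Concatenate two heavy-atom graphs; returns atoms, bonds and the offset of
# the second block.
.cat_graphs <- function(a, b) {
  off <- nrow(a$atoms)
  bonds_b <- b$bonds
  bonds_b$i <- bonds_b$i + off; bonds_b$j <- bonds_b$j + off
  list(atoms = dplyr::bind_rows(a$atoms, b$atoms),
       bonds = dplyr::bind_rows(a$bonds, bonds_b),
       offset = off)
}

.require_free_valence <- function(mol, idx, what) {
  if (idx < 1 || idx > n_atoms(mol) || mol$atoms$element[idx] == "H") {
    stop(what, ": atom ", idx, " is not a heavy atom")
  }
  if (n_hydrogens(mol, idx) < 1) {
    stop(what, ": atom ", idx, " (", mol$atoms$element[idx],
         ") has no hydrogen / free valence")
  }
}

#' Direct linkage: join two structures by a single bond
#'
#' One hydrogen is removed from each side and a single bond is formed between
#' the chosen atoms. Atom provenance of `a` is preserved; fragment atoms are
#' tagged `"new"`.
#'
#' @param a parent molecule; `ai` its attachment atom (must carry H).
#' @param b an `fg_fragment` (or molecule); `bi` its attachment atom.
#' @param ai,bi atom indices into the hydrogen-complete molecules.
#' @return the sanitized product molecule, or `NULL` if the product fails
#'   sanitization.
#' @export
link_direct <- function(a, ai, b, bi) {
  bmol <- if (inherits(b, "fg_fragment")) b$mol else b
  .require_free_valence(a, ai, "link_direct (a)")
  .require_free_valence(bmol, bi, "link_direct (b)")
  ha <- strip_hydrogens(a); hb <- strip_hydrogens(bmol)
  hb$atoms$provenance <- "new"
  g <- .cat_graphs(ha, hb)
  g$bonds <- dplyr::bind_rows(g$bonds, tibble::tibble(
    i = match(ai, ha$map), j = match(bi, hb$map) + g$offset,
    order = 1L, aromatic = FALSE, in_ring = FALSE))
  sanitize_molecule(g$atoms, g$bonds)
}

#' Linker-mediated bridge between two placed structures
#'
#' Connects `a` and `b` through a two-point linker fragment: `a` bonds to
#' the linker's first attachment point and `b` to its second. For an
#' asymmetric linker the caller enumerates both orientations by swapping
#' the linker's attachment vector.
#'
#' @param a,b molecules (typically two co-placed probes); `ai`, `bi` their
#'   attachment atoms.
#' @param linker an `fg_fragment` with role `"linker"` (exactly 2 points).
#' @param ai,bi atom indices.
#' @return sanitized product or `NULL`.
#' @export
link_via_linker <- function(a, ai, linker, b, bi) {
  stopifnot(inherits(linker, "fg_fragment"))
  if (length(linker$attachment) != 2) {
    stop("linker must have exactly 2 attachment points, got ", length(linker$attachment))
  }
  .require_free_valence(a, ai, "link_via_linker (a)")
  .require_free_valence(b, bi, "link_via_linker (b)")
  .require_free_valence(linker$mol, linker$attachment[1], "link_via_linker (linker)")
  .require_free_valence(linker$mol, linker$attachment[2], "link_via_linker (linker)")
  if (linker$attachment[1] == linker$attachment[2] &&
      n_hydrogens(linker$mol, linker$attachment[1]) < 2) {
    stop("link_via_linker: single-atom linker needs two free valences")
  }
  ha <- strip_hydrogens(a)
  hl <- strip_hydrogens(linker$mol); hl$atoms$provenance <- "new"
  hb <- strip_hydrogens(b)
  g1 <- .cat_graphs(ha, hl)
  g <- .cat_graphs(g1, hb)
  l1 <- match(linker$attachment[1], hl$map) + g1$offset
  l2 <- match(linker$attachment[2], hl$map) + g1$offset
  g$bonds <- dplyr::bind_rows(g$bonds, tibble::tibble(
    i = c(match(ai, ha$map), l2),
    j = c(l1, match(bi, hb$map) + g$offset),
    order = 1L, aromatic = FALSE, in_ring = FALSE))
  sanitize_molecule(g$atoms, g$bonds)
}

# Ring-size guard shared by fusion and spiro products.
.ring_size_ok <- function(mol, min_size = 3L, max_size = 8L) {
  sizes <- ring_bond_sizes(mol)
  sizes <- sizes[!is.na(sizes)]
  !length(sizes) || (min(sizes) >= min_size && max(sizes) <= max_size)
}

#' Ring fusion: merge two rings along a shared bond
#'
#' The two atoms of `bond_b` (a ring bond of the fragment) are identified
#' with the two atoms of `bond_a` (a ring bond of the parent), producing a
#' condensed ring system. Both atom mappings are attempted; each sanitizable
#' product within the ring-size bounds is returned.
#'
#' @param a parent molecule; `bond_a` index into `a$bonds` (must be a ring bond).
#' @param b fragment (or molecule); `bond_b` index into its bond table.
#' @param min_ring,max_ring allowed smallest-ring sizes in the product.
#' @return list of product molecules (possibly empty).
#' @export
fuse_rings <- function(a, bond_a, b, bond_b, min_ring = 3L, max_ring = 8L) {
  bmol <- if (inherits(b, "fg_fragment")) b$mol else b
  ba <- a$bonds[bond_a, ]; bb <- bmol$bonds[bond_b, ]
  if (!isTRUE(ba$in_ring)) stop("fuse_rings: bond_a is not a ring bond")
  if (!isTRUE(bb$in_ring)) stop("fuse_rings: bond_b is not a ring bond")
  ha <- strip_hydrogens(a)
  hb <- strip_hydrogens(bmol); hb$atoms$provenance <- "new"
  a1 <- match(ba$i, ha$map); a2 <- match(ba$j, ha$map)
  b1 <- match(bb$i, hb$map); b2 <- match(bb$j, hb$map)
  out <- list()
  for (mi in 1:2) {
    mapping <- if (mi == 1) c(b1, b2) else c(b2, b1)
    # element compatibility: identical elements at identified positions
    if (hb$atoms$element[mapping[1]] != ha$atoms$element[a1]) next
    if (hb$atoms$element[mapping[2]] != ha$atoms$element[a2]) next
    g <- .cat_graphs(ha, hb)
    m1 <- mapping[1] + g$offset; m2 <- mapping[2] + g$offset
    bonds <- g$bonds
    # drop the fragment copy of the fused bond, reroute the rest
    drop <- which((bonds$i == min(m1, m2) & bonds$j == max(m1, m2)))
    if (length(drop)) bonds <- bonds[-drop, , drop = FALSE]
    bonds$i[bonds$i == m1] <- a1; bonds$j[bonds$j == m1] <- a1
    bonds$i[bonds$i == m2] <- a2; bonds$j[bonds$j == m2] <- a2
    ii <- pmin(bonds$i, bonds$j); jj <- pmax(bonds$i, bonds$j)
    bonds$i <- ii; bonds$j <- jj
    # the fused bond keeps aromatic character if either side was aromatic,
    # so an aromatic ring fused onto an aliphatic one stays aromatic
    fk <- which(bonds$i == min(a1, a2) & bonds$j == max(a1, a2))
    if (length(fk)) bonds$aromatic[fk] <- isTRUE(ba$aromatic) || isTRUE(bb$aromatic)
    dup <- duplicated(paste(bonds$i, bonds$j))
    if (any(dup)) next  # identified atoms already shared another bond
    atoms <- g$atoms[-c(m1, m2), , drop = FALSE]
    # renumber after deleting the two fragment atoms
    remap <- cumsum(!seq_len(nrow(g$atoms)) %in% c(m1, m2))
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    mol <- sanitize_molecule(atoms, bonds)
    if (!is.null(mol) && .ring_size_ok(mol, min_ring, max_ring)) {
      attr(mol, "mapping") <- mi  # which atom identification produced it
      out[[length(out) + 1L]] <- mol
    }
  }
  out
}

#' Spiro junction: share one saturated ring atom between two rings
#'
#' Identifies a saturated (non-aromatic) ring atom of the fragment with a
#' saturated ring atom of the parent, producing a spiro center. Aromatic
#' atoms are rejected with an error (the rule is restricted to aliphatic
#' rings); a product with illegal valence is a rejection.
#'
#' @param a parent molecule; `atom_a` a saturated ring atom index.
#' @param b fragment (or molecule); `atom_b` its saturated ring atom.
#' @param min_ring,max_ring ring-size bounds for the product.
#' @return sanitized product or `NULL`.
#' @export
spiro_join <- function(a, atom_a, b, atom_b, min_ring = 3L, max_ring = 8L) {
  bmol <- if (inherits(b, "fg_fragment")) b$mol else b
  for (chk in list(list(a, atom_a, "atom_a"), list(bmol, atom_b, "atom_b"))) {
    m <- chk[[1]]; idx <- chk[[2]]
    if (!m$atoms$in_ring[idx]) stop("spiro_join: ", chk[[3]], " is not a ring atom")
    if (m$atoms$aromatic[idx]) stop("spiro_join: ", chk[[3]], " is aromatic; spiro is restricted to aliphatic rings")
  }
  ha <- strip_hydrogens(a)
  hb <- strip_hydrogens(bmol); hb$atoms$provenance <- "new"
  a1 <- match(atom_a, ha$map); b1 <- match(atom_b, hb$map)
  if (ha$atoms$element[a1] != hb$atoms$element[b1]) return(NULL)
  g <- .cat_graphs(ha, hb)
  m1 <- b1 + g$offset
  bonds <- g$bonds
  bonds$i[bonds$i == m1] <- a1; bonds$j[bonds$j == m1] <- a1
  ii <- pmin(bonds$i, bonds$j); jj <- pmax(bonds$i, bonds$j)
  bonds$i <- ii; bonds$j <- jj
  if (any(duplicated(paste(bonds$i, bonds$j))) || any(bonds$i == bonds$j)) return(NULL)
  atoms <- g$atoms[-m1, , drop = FALSE]
  remap <- cumsum(seq_len(nrow(g$atoms)) != m1)
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  mol <- sanitize_molecule(atoms, bonds)
  if (is.null(mol) || !.ring_size_ok(mol, min_ring, max_ring)) return(NULL)
  mol
}

# Saturated ring atoms usable for spiro (>= 2 hydrogens so the merged center
# can carry 4 ring bonds).
spiro_sites <- function(mol) {
  hv <- heavy_atoms(mol)
  hv[mol$atoms$in_ring[hv] & !mol$atoms$aromatic[hv] &
       vapply(hv, function(a) n_hydrogens(mol, a) >= 2, logical(1))]
}

# Ring bonds of a molecule usable for fusion: legality is finally decided
# by sanitization, so every ring bond is offered, optionally reduced to one
# representative per symmetry orbit (benzene: 6 equivalent bonds -> 1).
fusion_bonds <- function(mol, symmetry_reduce = FALSE) {
  ks <- which(mol$bonds$in_ring)
  if (!symmetry_reduce || length(ks) < 2) return(ks)
  hv <- heavy_atoms(mol)
  auts <- heavy_automorphisms(mol)
  key0 <- paste(match(mol$bonds$i[ks], hv), match(mol$bonds$j[ks], hv))
  orbit_key <- vapply(seq_along(ks), function(q) {
    i0 <- match(mol$bonds$i[ks[q]], hv); j0 <- match(mol$bonds$j[ks[q]], hv)
    imgs <- vapply(auts, function(p) {
      a <- p[i0]; b <- p[j0]
      paste(min(a, b), max(a, b))
    }, character(1))
    min(imgs)
  }, character(1))
  ks[!duplicated(orbit_key)]
}

#' Grow candidate structures from parents and a fragment library
#'
#' Applies every enabled linking rule at every legal (site x fragment x
#' site) combination. The linker rule runs only in probe-probe context:
#' `pair_context` supplies rows of co-placed parent pairs. Products are
#' deduplicated by canonical SMILES; every candidate carries a complete
#' lineage record sufficient to replay the construction
#' ([replay_lineage()]).
#'
#' @param parents candidate tibble (needs `id`, `mol`, `iteration` columns).
#' @param library list of `fg_fragment`s.
#' @param rules character subset of `c("direct", "linker", "fuse", "spiro")`.
#' @param pair_context optional tibble with columns `id_a`, `id_b` naming
#'   parent pairs eligible for the linker rule.
#' @param symmetry_reduce reduce attachment sites by graph symmetry.
#' @param min_ring,max_ring ring-size guard for fusion/spiro products.
#' @return candidate tibble (`id`, `smiles`, `mol`, `iteration`, `rule`,
#'   `parents`, `fragment_id`, `detail`); attribute `"tally"` holds per-rule
#'   generated/rejected counts.
#' @export
grow <- function(parents, library, rules = c("direct", "linker", "fuse", "spiro"),
                 pair_context = NULL, symmetry_reduce = TRUE,
                 min_ring = 3L, max_ring = 8L) {
  stopifnot(nrow(parents) >= 1)
  rules <- intersect(rules, c("direct", "linker", "fuse", "spiro"))
  rows <- list()
  tally <- c(direct = 0L, linker = 0L, fuse = 0L, spiro = 0L)
  reject <- c(direct = 0L, linker = 0L, fuse = 0L, spiro = 0L)
  add <- function(mol, rule, parent_ids, fragment_id, detail, iteration) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      smiles = canonical_smiles(mol), mol = list(mol),
      iteration = iteration, rule = rule, parents = list(parent_ids),
      fragment_id = fragment_id, detail = detail)
  }
  frag_sites <- lapply(library, function(f) f$attachment)

  # identical parent molecules produce identical product graphs; enumerate
  # each molecule once (the first, best-ranked pose keeps the lineage)
  parent_smiles <- vapply(parents$mol, canonical_smiles, character(1))
  parent_idx <- which(!duplicated(parent_smiles))

  for (p in parent_idx) {
    pmol <- parents$mol[[p]]
    pid <- parents$id[p]
    it <- parents$iteration[p] + 1L
    pmol$atoms$provenance <- ifelse(pmol$atoms$element == "H", "new",
                                    paste0(pid, ":", seq_len(n_atoms(pmol))))
    sitesA <- enumerate_attachment_points(pmol, symmetry_reduce = symmetry_reduce)

    if ("direct" %in% rules) {
      for (fi in seq_along(library)) {
        f <- library[[fi]]
        if (f$role == "linker") next
        for (ai in sitesA) for (bi in frag_sites[[fi]]) {
          tally["direct"] <- tally["direct"] + 1L
          child <- link_direct(pmol, ai, f, bi)
          if (is.null(child)) reject["direct"] <- reject["direct"] + 1L
          else add(child, "direct", pid, f$id, paste0(ai, ">", bi), it)
        }
      }
    }
    if ("fuse" %in% rules) {
      pb <- fusion_bonds(pmol, symmetry_reduce = symmetry_reduce)
      for (fi in seq_along(library)) {
        f <- library[[fi]]
        if (f$role == "linker") next
        fb <- fusion_bonds(f$mol, symmetry_reduce = symmetry_reduce)
        for (ka in pb) for (kb in fb) {
          prods <- tryCatch(fuse_rings(pmol, ka, f, kb, min_ring, max_ring),
                            error = function(e) list())
          tally["fuse"] <- tally["fuse"] + 2L
          reject["fuse"] <- reject["fuse"] + 2L - length(prods)
          for (child in prods) {
            add(child, "fuse", pid, f$id,
                paste0("b", ka, ">b", kb, ">m", attr(child, "mapping")), it)
          }
        }
      }
    }
    if ("spiro" %in% rules) {
      sa <- spiro_sites(pmol)
      if (symmetry_reduce && length(sa) > 1) {
        orb <- heavy_orbits(pmol)
        sa <- sa[!duplicated(orb[match(sa, heavy_atoms(pmol))])]
      }
      for (fi in seq_along(library)) {
        f <- library[[fi]]
        if (f$role == "linker") next
        sb <- spiro_sites(f$mol)
        if (symmetry_reduce && length(sb) > 1) {
          orb <- heavy_orbits(f$mol)
          sb <- sb[!duplicated(orb[match(sb, heavy_atoms(f$mol))])]
        }
        for (ia in sa) for (ib in sb) {
          tally["spiro"] <- tally["spiro"] + 1L
          child <- tryCatch(spiro_join(pmol, ia, f, ib, min_ring, max_ring),
                            error = function(e) NULL)
          if (is.null(child)) reject["spiro"] <- reject["spiro"] + 1L
          else add(child, "spiro", pid, f$id, paste0(ia, "~", ib), it)
        }
      }
    }
  }

  if ("linker" %in% rules && !is.null(pair_context) && nrow(pair_context)) {
    linkers <- library[vapply(library, function(f) f$role == "linker", logical(1))]
    for (q in seq_len(nrow(pair_context))) {
      ia <- match(pair_context$id_a[q], parents$id)
      ib <- match(pair_context$id_b[q], parents$id)
      if (is.na(ia) || is.na(ib)) next
      ma <- parents$mol[[ia]]; mb <- parents$mol[[ib]]
      ma$atoms$provenance <- ifelse(ma$atoms$element == "H", "new",
                                    paste0(parents$id[ia], ":", seq_len(n_atoms(ma))))
      mb$atoms$provenance <- ifelse(mb$atoms$element == "H", "new",
                                    paste0(parents$id[ib], ":", seq_len(n_atoms(mb))))
      it <- max(parents$iteration[c(ia, ib)]) + 1L
      sA <- enumerate_attachment_points(ma, symmetry_reduce = symmetry_reduce)
      sB <- enumerate_attachment_points(mb, symmetry_reduce = symmetry_reduce)
      for (lf in linkers) {
        orients <- list(lf$attachment, rev(lf$attachment))
        for (ori in seq_along(orients)) {
          l2 <- lf; l2$attachment <- orients[[ori]]
          for (ai in sA) for (bi in sB) {
            tally["linker"] <- tally["linker"] + 1L
            child <- tryCatch(link_via_linker(ma, ai, l2, mb, bi),
                              error = function(e) NULL)
            if (is.null(child)) reject["linker"] <- reject["linker"] + 1L
            else add(child, "linker", c(parents$id[ia], parents$id[ib]), lf$id,
                     paste0(ai, ">", "o", ori, ">", bi), it)
          }
        }
      }
    }
  }

  if (!length(rows)) {
    out <- tibble::tibble(id = character(), smiles = character(), mol = list(),
                          iteration = integer(), rule = character(), parents = list(),
                          fragment_id = character(), detail = character())
    attr(out, "tally") <- list(generated = tally, rejected = reject, duplicates = 0L)
    return(out)
  }
  out <- dplyr::bind_rows(rows)
  # a product reachable from two different parent molecules keeps one record
  # per parent molecule, so each lineage can later be scored on its own
  # parent pose; true duplicates (same product, same parent) collapse
  parent_of <- vapply(out$parents, function(p) paste(sort(p), collapse = "+"), character(1))
  dups <- duplicated(paste(out$smiles, parent_of))
  n_dup <- sum(dups)
  out <- out[!dups, , drop = FALSE]
  out$id <- paste0("g", out$iteration, "_", seq_len(nrow(out)))
  out <- out[, c("id", "smiles", "mol", "iteration", "rule", "parents",
                 "fragment_id", "detail")]
  attr(out, "tally") <- list(generated = tally, rejected = reject, duplicates = n_dup)
  out
}

#' Replay a candidate's lineage
#'
#' Re-applies the recorded rule to the recorded parents and fragment and
#' returns the canonical SMILES of the reconstruction; equality with the
#' candidate's own SMILES is the lineage integrity check.
#'
#' @param cand one-row candidate tibble (from [grow()]).
#' @param parents the parent candidate tibble the candidate was grown from.
#' @param library the fragment library used.
#' @return canonical SMILES of the replayed product.
#' @export
replay_lineage <- function(cand, parents, library) {
  frag <- NULL
  for (f in library) if (identical(f$id, cand$fragment_id)) { frag <- f; break }
  pids <- cand$parents[[1]]
  pa <- parents$mol[[match(pids[1], parents$id)]]
  detail <- cand$detail
  if (cand$rule == "direct") {
    parts <- as.integer(strsplit(detail, ">", fixed = TRUE)[[1]])
    child <- link_direct(pa, parts[1], frag, parts[2])
  } else if (cand$rule == "fuse") {
    parts <- strsplit(detail, ">", fixed = TRUE)[[1]]
    ka <- as.integer(sub("b", "", parts[1])); kb <- as.integer(sub("b", "", parts[2]))
    prods <- fuse_rings(pa, ka, frag, kb)
    smis <- vapply(prods, canonical_smiles, character(1))
    if (cand$smiles %in% smis) return(cand$smiles)
    return(if (length(smis)) smis[1] else NA_character_)
  } else if (cand$rule == "spiro") {
    parts <- as.integer(strsplit(detail, "~", fixed = TRUE)[[1]])
    child <- spiro_join(pa, parts[1], frag, parts[2])
  } else if (cand$rule == "linker") {
    pb <- parents$mol[[match(pids[2], parents$id)]]
    parts <- strsplit(detail, ">", fixed = TRUE)[[1]]
    ai <- as.integer(parts[1]); bi <- as.integer(parts[3])
    ori <- as.integer(sub("o", "", parts[2]))
    l2 <- frag
    if (ori == 2) l2$attachment <- rev(l2$attachment)
    child <- link_via_linker(pa, ai, l2, pb, bi)
  } else {
    stop("unknown rule: ", cand$rule)
  }
  if (is.null(child)) return(NA_character_)
  canonical_smiles(child)
}

#' Read a fragment library from a SMILES file
#'
#' One fragment per line: `SMILES [linker] [id]`, `#` comments allowed.
#' Attachment points may be marked with `[*]` dummy atoms (explicit markers
#' win); otherwise any hydrogen-bearing heavy atom is an implicit attachment
#' point.
#'
#' @param path file path.
#' @return list of `fg_fragment`s.
#' @export
read_fragment_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    smi <- tok[1]
    role <- if (length(tok) > 1 && tok[2] == "linker") "linker" else "building_block"
    id <- if (length(tok) > 1 && tok[length(tok)] != "linker") tok[length(tok)] else NULL
    out[[length(out) + 1L]] <- fragment_from_smiles(smi, role = role, id = id)
  }
  out
}

#' Build a fragment from SMILES (dummy-atom attachment markers honored)
#' @param smiles SMILES, optionally with `[*]` attachment markers.
#' @param role,id see [fragment()].
#' @export
fragment_from_smiles <- function(smiles, role = "building_block", id = NULL) {
  if (grepl("*", smiles, fixed = TRUE)) {
    mol <- parse_dummy_smiles(smiles)
    fragment(mol$mol, attachment = mol$attachment, role = role, id = id %||% smiles)
  } else {
    fragment(parse_molecule(smiles), role = role, id = id)
  }
}

# Parse SMILES containing [*] markers: dummies are removed and their heavy
# neighbors recorded as attachment points.
parse_dummy_smiles <- function(smiles) {
  mb <- ob_convert("SMI", "SDF", paste0(smiles, "\n"))
  p <- parse_molblock(mb)
  dummies <- which(p$atoms$element %in% c("*", "Du", "Xx", "R"))
  if (!length(dummies)) {
    mol <- parse_molecule(smiles)
    return(list(mol = mol, attachment = enumerate_attachment_points(mol)))
  }
  anchors0 <- vapply(dummies, function(d) {
    nb <- c(p$bonds$j[p$bonds$i == d], p$bonds$i[p$bonds$j == d])
    nb[1]
  }, integer(1))
  keep <- setdiff(seq_len(nrow(p$atoms)), dummies)
  remap <- match(seq_len(nrow(p$atoms)), keep)
  atoms <- p$atoms[keep, , drop = FALSE]
  bonds <- p$bonds[p$bonds$i %in% keep & p$bonds$j %in% keep, , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  mol <- sanitize_molecule(atoms, bonds)
  if (is.null(mol)) stop("cannot sanitize fragment SMILES: ", smiles)
  # anchors are heavy atoms and keep their relative order under sanitize
  hv <- heavy_atoms(mol)
  list(mol = mol, attachment = hv[remap[anchors0]])
}
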