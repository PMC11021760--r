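# Interaction fingerprints, binding-mode clustering, and candidate
# selection (with or without IFP diversification).

.IFP_KINDS <- c("hb_donor_to_ligand", "hb_acceptor_from_ligand",
                "hydrophobic", "aromatic", "ionic")

# Protein-side charged atoms for the ionic bit, typed by residue/atom name.
.charged_protein_atoms <- function(atoms) {
  plus <- (atoms$resname == "LYS" & atoms$atom_name == "NZ") |
          (atoms$resname == "ARG" & atoms$atom_name %in% c("NH1", "NH2", "NE"))
  minus <- (atoms$resname == "ASP" & atoms$atom_name %in% c("OD1", "OD2")) |
           (atoms$resname == "GLU" & atoms$atom_name %in% c("OE1", "OE2"))
  list(plus = which(plus), minus = which(minus))
}

#' Compute the interaction fingerprint of a pose
#'
#' A fixed-layout bitvector over (pocket residue x interaction kind). A bit
#' is set when the residue-ligand contact of that kind satisfies the same
#' geometric windows used by the energy model (single source of truth). The
#' ionic bit requires formal charges of opposite sign within the model's
#' ionic distance.
#'
#' @param mol,xyz the posed ligand.
#' @param pocket an `fg_pocket`.
#' @param hotspots hotspot tibble for the pocket.
#' @param model energy model.
#' @return an `fg_ifp`: logical vector with a `layout` attribute
#'   (data.frame of residue/kind per position).
#' @export
compute_ifp <- function(mol, xyz, pocket, hotspots, model = default_energy_model()) {
  residues <- pocket$residues
  layout <- expand.grid(kind = .IFP_KINDS, reskey = residues,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  layout <- layout[order(layout$reskey, layout$kind), c("reskey", "kind")]
  bits <- rep(FALSE, nrow(layout))
  feats <- ligand_features(mol, xyz)
  ct <- contact_table(feats, hotspots, model)
  if (nrow(ct)) {
    kind_map <- c(hb_donor = "hb_donor_to_ligand",
                  hb_acceptor = "hb_acceptor_from_ligand",
                  aromatic_ring = "aromatic",
                  hydrophobic_patch = "hydrophobic")
    keys <- paste(ct$reskey, kind_map[ct$kind])
    bits[match(unique(keys), paste(layout$reskey, layout$kind))] <- TRUE
  }
  # ionic contacts
  lig_charge <- mol$atoms$charge
  charged_idx <- which(lig_charge != 0 & mol$atoms$element != "H")
  if (length(charged_idx)) {
    patoms <- pocket_atoms(pocket)
    pc <- .charged_protein_atoms(patoms)
    for (a in charged_idx) {
      partner <- if (lig_charge[a] > 0) pc$minus else pc$plus
      if (!length(partner)) next
      d <- sqrt(rowSums(sweep(cbind(patoms$x, patoms$y, patoms$z)[partner, , drop = FALSE],
                              2, xyz[a, ])^2))
      hit <- partner[d <= model$ionic_dist_max]
      if (length(hit)) {
        keys <- paste(unique(patoms$reskey[hit]), "ionic")
        bits[match(keys, paste(layout$reskey, layout$kind))] <- TRUE
      }
    }
  }
  structure(bits, layout = layout, class = "fg_ifp")
}

#' Tanimoto similarity of two interaction fingerprints
#'
#' `|a & b| / |a | b|`; defined as 1 when both fingerprints are empty.
#' Fingerprints must share the same layout.
#'
#' @param a,b `fg_ifp` objects (or plain logical vectors of equal length).
#' @return numeric in `[0, 1]`.
#' @export
ifp_tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprints have different layouts")
  la <- attr(a, "layout"); lb <- attr(b, "layout")
  if (!is.null(la) && !is.null(lb) && !identical(la, lb)) {
    stop("fingerprints have different layouts")
  }
  u <- sum(a | b)
  if (u == 0) return(1.0)
  sum(a & b) / u
}

#' Leader clustering of interaction fingerprints
#'
#' Fingerprints are processed in input order; each joins the first cluster
#' whose leader similarity is at least `threshold`, otherwise it founds a
#' new cluster. Deterministic; the input order is part of the definition
#' (the pipeline feeds candidates in descending score order so leaders are
#' strong poses).
#'
#' @param fps list of fingerprints with identical layouts.
#' @param threshold Tanimoto similarity threshold (default 0.6).
#' @return integer vector: cluster id per input (1-based, order of founding).
#' @export
cluster_ifps <- function(fps, threshold = 0.6) {
  n <- length(fps)
  if (!n) return(integer())
  leaders <- integer()
  assignment <- integer(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (ci in seq_along(leaders)) {
      if (ifp_tanimoto(fps[[leaders[ci]]], fps[[i]]) >= threshold) {
        assignment[i] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      leaders <- c(leaders, i)
      assignment[i] <- length(leaders)
    }
  }
  attr(assignment, "leaders") <- leaders
  assignment
}

#' Select candidates by score, optionally diversified by IFP clustering
#'
#' Plain mode returns the top `k` by the objective (binding energy
#' ascending, PLI score descending), ties broken by canonical SMILES.
#' IFP-clustered mode first orders candidates by the objective, clusters
#' their fingerprints (leader algorithm), keeps the best candidate of each
#' cluster, and returns the top `k` representatives.
#'
#' @param cands candidate tibble; must carry the objective column, and an
#'   `ifp` list-column when `mode = "ifp_clustered"`.
#' @param objective `"binding_energy"` or `"pli_score"`.
#' @param mode `"plain"` or `"ifp_clustered"`.
#' @param k number of candidates to return.
#' @param threshold IFP similarity threshold for clustering.
#' @return candidate tibble sorted by the objective (with a `cluster` column
#'   in clustered mode).
#' @export
select_candidates <- function(cands, objective = c("binding_energy", "pli_score"),
                              mode = c("plain", "ifp_clustered"), k = 10L,
                              threshold = 0.6) {
  objective <- match.arg(objective)
  mode <- match.arg(mode)
  stopifnot(k >= 1)
  if (!nrow(cands)) return(cands)
  if (!objective %in% names(cands) || anyNA(cands[[objective]])) {
    stop("unscored candidate: every candidate needs a ", objective, " value")
  }
  ord <- if (objective == "binding_energy") {
    order(cands$binding_energy, cands$smiles)
  } else {
    order(-cands$pli_score, cands$smiles)
  }
  cands <- cands[ord, , drop = FALSE]
  if (mode == "plain") return(utils::head(cands, k))
  if (!"ifp" %in% names(cands) || any(vapply(cands$ifp, is.null, logical(1)))) {
    stop("ifp_clustered selection needs an 'ifp' list-column on every candidate")
  }
  cl <- cluster_ifps(cands$ifp, threshold = threshold)
  cands$cluster <- as.integer(cl)
  reps <- cands[!duplicated(cands$cluster), , drop = FALSE]  # first = best per cluster
  utils::head(reps, k)
}

#' Export fingerprints as a matrix
#'
#' @param cands candidate tibble with `ifp` list-column and `id`.
#' @return 0/1 integer matrix, rows = candidate ids, columns = residue x kind.
#' @export
ifp_matrix <- function(cands) {
  stopifnot(nrow(cands) >= 1)
  layout <- attr(cands$ifp[[1]], "layout")
  m <- do.call(rbind, lapply(cands$ifp, as.integer))
  rownames(m) <- cands$id
  colnames(m) <- paste(layout$reskey, layout$kind, sep = "|")
  m
}
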