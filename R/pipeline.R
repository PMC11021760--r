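# End-to-end orchestration: probe placement, iterative growth, filtering,
# scoring, selection, final output, and the regrow-and-reproduce benchmark.

#' Fragment a ligand by breaking ring-connected bonds
#'
#' Cleaves every acyclic single bond having at least one ring-atom endpoint,
#' with two exemptions: amide C-N bonds are never cut (stable pharmacophoric
#' unit), and terminal single-heavy-atom substituents (methyl, halogen,
#' hydroxyl) stay attached — they are decorations, not fragments. Open
#' valences are hydrogen-capped. Acyclic pieces isolated between two cuts
#' become linker-role fragments automatically.
#'
#' @param mol the ligand.
#' @param cut_terminal also cut terminal single-heavy-atom substituents.
#' @param cut_amide also cut amide C-N bonds.
#' @return list of `fg_fragment`s; each carries `src_atoms`, the original
#'   ligand atom indices of its heavy atoms (in order), for crystal-pose
#'   probe geometry.
#' @export
fragment_ligand <- function(mol, cut_terminal = FALSE, cut_amide = FALSE) {
  b <- mol$bonds
  hv <- heavy_atoms(mol)
  g <- igraph::make_empty_graph(n_atoms(mol), directed = FALSE)
  heavy_bonds <- which(b$i %in% hv & b$j %in% hv)
  g <- igraph::add_edges(g, t(as.matrix(b[heavy_bonds, c("i", "j")])))
  is_amide_cn <- function(i, j) {
    for (swap in list(c(i, j), c(j, i))) {
      c0 <- swap[1]; n0 <- swap[2]
      if (mol$atoms$element[c0] == "C" && mol$atoms$element[n0] == "N") {
        k <- which((b$i == c0 | b$j == c0) & b$order == 2L)
        if (any(mol$atoms$element[setdiff(c(b$i[k], b$j[k]), c0)] == "O")) return(TRUE)
      }
    }
    FALSE
  }
  cuts <- integer()
  for (kk in seq_along(heavy_bonds)) {
    k <- heavy_bonds[kk]
    if (b$order[k] != 1L || b$aromatic[k] || b$in_ring[k]) next
    if (!(mol$atoms$in_ring[b$i[k]] || mol$atoms$in_ring[b$j[k]])) next
    if (!cut_amide && is_amide_cn(b$i[k], b$j[k])) next
    if (!cut_terminal) {
      g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(b$i[k], b$j[k])))
      comp <- igraph::components(g2)$membership
      sides <- c(sum(comp[hv] == comp[b$i[k]]), sum(comp[hv] == comp[b$j[k]]))
      if (min(sides) <= 1) next  # terminal decoration
    }
    cuts <- c(cuts, k)
  }
  gcut <- g
  for (k in cuts) {
    gcut <- igraph::delete_edges(gcut, igraph::get_edge_ids(gcut, c(b$i[k], b$j[k])))
  }
  comp <- igraph::components(gcut)$membership
  out <- list()
  for (cid in sort(unique(comp[hv]))) {
    members <- hv[comp[hv] == cid]
    sub_b <- b[b$i %in% members & b$j %in% members, , drop = FALSE]
    remap <- match(seq_len(n_atoms(mol)), members)
    atoms <- mol$atoms[members, , drop = FALSE]
    atoms$provenance <- "new"
    bonds <- sub_b
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    fmol <- sanitize_molecule(atoms, bonds)
    if (is.null(fmol)) stop("fragmentation produced an unsanitizable piece")
    # attachment points: members that lost a cut bond
    cut_atoms <- unique(unlist(lapply(cuts, function(k) {
      ends <- c(b$i[k], b$j[k]); ends[ends %in% members]
    })))
    att_pos <- integer()
    for (ca in cut_atoms) {
      # one attachment entry per cut bond ending at this atom
      n_cuts_here <- sum(vapply(cuts, function(k) b$i[k] == ca || b$j[k] == ca, logical(1)))
      att_pos <- c(att_pos, rep(heavy_atoms(fmol)[remap[ca]], n_cuts_here))
    }
    role <- if (length(att_pos) == 2 && !any(atoms$in_ring)) "linker" else "building_block"
    fr <- fragment(fmol, attachment = if (length(att_pos)) sort(att_pos) else NULL,
                   role = role, id = paste0("frag", cid))
    fr$src_atoms <- members
    out[[length(out) + 1L]] <- fr
  }
  out
}

#' Classify a pose-reproduction RMSD
#'
#' Below 2 angstroms the crystal pose counts as reproduced; between 2 and
#' 4.5 as almost reproduced; above 4.5 as failed.
#'
#' @param rmsd RMSD in angstroms (vectorized).
#' @return character vector: `"reproduced"`, `"almost"` or `"failed"`.
#' @export
classify_reproduction <- function(rmsd) {
  out <- character(length(rmsd))
  out[rmsd < 2] <- "reproduced"
  out[rmsd >= 2 & rmsd <= 4.5] <- "almost"
  out[rmsd > 4.5] <- "failed"
  out
}

#' Generation configuration
#'
#' Collects every tunable of a generation run in one validated record.
#'
#' @param probes probe set: list of `fg_fragment`s / molecules, SMILES
#'   vector, or path to a SMILES library file.
#' @param library building-block library (same forms as `probes`).
#' @param rules enabled linking rules.
#' @param objective selection score: `"binding_energy"` or `"pli_score"`.
#' @param selection_mode `"plain"` or `"ifp_clustered"`.
#' @param k structures kept per iteration.
#' @param k_probes placed probes kept after the non-iterative stage.
#' @param max_iterations growth iterations.
#' @param mw_ceiling stop criterion: candidates above this mass (Da) are not
#'   grown further.
#' @param n_conformers conformers per candidate.
#' @param n_probe_conformers conformers per probe at placement.
#' @param pocket_cutoff pocket shell radius (angstroms).
#' @param seed master seed; all stage seeds derive from it.
#' @param ifp_threshold similarity threshold for IFP clustering.
#' @param dock_restarts rigid-docking perturbation restarts.
#' @param dock_top assembled poses per candidate forwarded to rigid docking.
#' @param dock_maxit optimizer iterations per docking start.
#' @param polish_top candidates per iteration re-docked with the generous
#'   budget after the first scoring pass (two-tier docking).
#' @param polish_maxit optimizer iterations for the polishing stage.
#' @param linker_max_dist max centroid distance (angstroms) for a probe pair
#'   to be eligible for the linker rule.
#' @param model energy model ([default_energy_model()]).
#' @param filter_rules filter rule set ([load_filter_rules()]).
#' @param refiner pose refiner ([default_refiner()] or [xtb_refiner()]).
#' @return an `fg_config` list.
#' @export
generation_config <- function(probes, library,
                              rules = c("direct", "linker", "fuse", "spiro"),
                              objective = "binding_energy",
                              selection_mode = "plain",
                              k = 8L, k_probes = 4L, max_iterations = 2L,
                              mw_ceiling = 550, n_conformers = 6L,
                              n_probe_conformers = 2L, pocket_cutoff = 5.0,
                              seed = 1L, ifp_threshold = 0.6,
                              dock_restarts = 2L, dock_top = 2L,
                              dock_maxit = 60L, polish_top = 6L, polish_maxit = 300L,
                              linker_max_dist = 12.0,
                              model = default_energy_model(),
                              filter_rules = default_filter_rules(),
                              refiner = default_refiner()) {
  as_frags <- function(x, role) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      return(read_fragment_library(x))
    }
    if (is.character(x)) {
      return(lapply(seq_along(x), function(i) {
        fragment_from_smiles(x[i], role = role, id = paste0(role, i))
      }))
    }
    lapply(seq_along(x), function(i) {
      xi <- x[[i]]
      if (inherits(xi, "fg_fragment")) xi
      else fragment(xi, role = role, id = paste0(role, i))
    })
  }
  stopifnot(max_iterations >= 1, k >= 1, k_probes >= 1, n_conformers >= 1)
  objective <- match.arg(objective, c("binding_energy", "pli_score"))
  selection_mode <- match.arg(selection_mode, c("plain", "ifp_clustered"))
  structure(list(
    probes = as_frags(probes, "probe"),
    library = as_frags(library, "building_block"),
    rules = rules, objective = objective, selection_mode = selection_mode,
    k = as.integer(k), k_probes = as.integer(k_probes),
    max_iterations = as.integer(max_iterations), mw_ceiling = mw_ceiling,
    n_conformers = as.integer(n_conformers),
    n_probe_conformers = as.integer(n_probe_conformers),
    pocket_cutoff = pocket_cutoff, seed = as.integer(seed),
    ifp_threshold = ifp_threshold, dock_restarts = as.integer(dock_restarts),
    dock_top = as.integer(dock_top), dock_maxit = as.integer(dock_maxit),
    polish_top = as.integer(polish_top), polish_maxit = as.integer(polish_maxit),
    linker_max_dist = linker_max_dist,
    model = model, filter_rules = filter_rules, refiner = refiner
  ), class = "fg_config")
}

# Inherited-atom map of a candidate: rows (child_atom, ref_row) against a
# reference matrix stacked from its parents' poses.
.lineage_map <- function(child_mol, parent_rows) {
  prov <- child_mol$atoms$provenance
  ref <- NULL
  map <- NULL
  offset <- 0L
  for (p in seq_len(nrow(parent_rows))) {
    pid <- parent_rows$id[p]
    pose <- parent_rows$pose[[p]]
    tagged <- grep(paste0("^", pid, ":"), prov)
    if (length(tagged)) {
      parent_atom <- as.integer(sub(paste0("^", pid, ":"), "", prov[tagged]))
      ref <- rbind(ref, pose[parent_atom, , drop = FALSE])
      map <- rbind(map, cbind(tagged, offset + seq_along(tagged)))
      offset <- offset + length(tagged)
    }
  }
  list(map = map, ref = ref)
}

# Score one candidate. Children of single-parent rules (direct, fuse,
# spiro) get their poses assembled geometrically on the parent pose with
# junction-torsion sampling; linker children (and any assembly failure)
# fall back to full conformer embedding plus alignment onto the parent
# pose(s). The best assembled/aligned poses are then rigid-docked.
.score_candidate <- function(cand_row, parent_rows, pocket, hotspots, config,
                             frag_cache, alt_poses = list()) {
  mol <- cand_row$mol[[1]]
  rule <- cand_row$rule
  frag <- NULL
  for (f in config$library) if (identical(f$id, cand_row$fragment_id)) { frag <- f; break }

  poses <- list()
  if (rule %in% c("direct", "fuse", "spiro") && !is.null(frag)) {
    # assemble from every available pose of the parent molecule (the same
    # probe is often placed at several sites; the full-molecule energy then
    # decides which placement carries the child)
    parent_mol <- parent_rows$mol[[1]]
    frag_confs <- tryCatch(
      .fragment_conformers(frag, frag_cache, config$seed),
      error = function(e) NULL)
    if (!is.null(frag_confs)) {
      parts <- strsplit(cand_row$detail, ">", fixed = TRUE)[[1]]
      parent_poses <- c(parent_rows$pose[1], alt_poses)
      parent_poses <- parent_poses[vapply(parent_poses, function(p) {
        is.matrix(p) && nrow(p) == n_atoms(parent_mol)
      }, logical(1))]
      for (pp in seq_along(parent_poses)) {
        parent_pose <- parent_poses[[pp]]
        new_poses <- tryCatch(switch(rule,
          direct = assemble_direct(mol, parent_mol, parent_pose,
                                   as.integer(parts[1]), frag, as.integer(parts[2]),
                                   frag_confs, n_torsions = 3L),
          fuse = {
            ka <- as.integer(sub("b", "", parts[1]))
            kb <- as.integer(sub("b", "", parts[2]))
            mi <- as.integer(sub("m", "", parts[3]))
            bb <- frag$mol$bonds[kb, ]
            mapping <- if (mi == 1) c(bb$i, bb$j) else c(bb$j, bb$i)
            assemble_fuse(mol, parent_mol, parent_pose, ka, frag, mapping, frag_confs)
          },
          spiro = {
            ps <- as.integer(strsplit(cand_row$detail, "~", fixed = TRUE)[[1]])
            assemble_spiro(mol, parent_mol, parent_pose, ps[1], frag, ps[2], frag_confs)
          }), error = function(e) list())
        poses <- c(poses, new_poses)
      }
    }
  }
  if (!length(poses)) {
    # embedding path: conformers aligned onto the parent pose(s)
    lm <- .lineage_map(mol, parent_rows)
    if (is.null(lm$map) || nrow(lm$map) < 3) return(NULL)
    confs <- tryCatch(
      generate_conformers(mol, n = config$n_conformers,
                          seed = derive_seed(config$seed, "conf", cand_row$smiles)),
      error = function(e) NULL)
    if (is.null(confs)) return(NULL)
    poses <- lapply(confs, function(cf) align_to_parent(cf, lm$ref, lm$map)$xyz)
  }
  flex <- make_flex_scorer(mol, pocket, hotspots, config$model)
  energies <- vapply(poses, flex, numeric(1))
  ord <- order(energies)
  top <- ord[seq_len(min(config$dock_top, length(ord)))]
  best <- NULL
  for (ti in seq_along(top)) {
    if (rule == "direct" && length(poses) && !is.null(frag) && nrow(parent_rows) == 1) {
      # direct children keep the junction torsion as a seventh docking DOF
      parent_mol <- parent_rows$mol[[1]]
      parts <- strsplit(cand_row$detail, ">", fixed = TRUE)[[1]]
      hv_p <- heavy_atoms(parent_mol); hv_c <- heavy_atoms(mol)
      hv_f <- heavy_atoms(frag$mol)
      a_child <- hv_c[match(as.integer(parts[1]), hv_p)]
      b_child <- hv_c[length(hv_p) + match(as.integer(parts[2]), hv_f)]
      dk <- dock_with_torsion(mol, poses[[top[ti]]], c(a_child, b_child),
                              torsion_movers(mol), flex,
                              maxit = 2L * config$dock_maxit)
      det <- binding_energy(mol, dk$xyz, pocket, hotspots, config$model, detail = TRUE)
      dk$clash <- det$clash
    } else {
      dk <- rigid_dock(mol, poses[[top[ti]]], pocket, hotspots, config$model,
                       seed = derive_seed(config$seed, "dock", cand_row$smiles, ti),
                       n_restarts = config$dock_restarts, maxit = config$dock_maxit)
    }
    if (is.null(best) || dk$energy < best$energy) {
      best <- list(xyz = dk$xyz, energy = dk$energy, clash = dk$clash)
    }
  }
  pli <- pli_score(mol, best$xyz, pocket, hotspots, config$model)
  fp <- compute_ifp(mol, best$xyz, pocket, hotspots, config$model)
  list(pose = best$xyz, binding_energy = best$energy, pli_score = pli,
       clash = best$clash, ifp = fp)
}

#' Run a full generation experiment
#'
#' Executes the non-iterative stage (probe placement, refinement,
#' selection) and then grows structures for up to `max_iterations` rounds:
#' link, filter (core rules), embed conformers, align to the parent pose,
#' rigid-dock, score and select. Growth stops at the iteration cap or when
#' no candidate below the molecular-weight ceiling survives. The final pool
#' (probes plus all scored candidates) passes the enhanced filter and
#' carries binding energy, PLI score and shape similarity against the
#' reference ligand. Fully deterministic given the config seed.
#'
#' @param protein an `fg_protein`, or a PDB file path.
#' @param reference the reference ligand defining the pocket: a molecule
#'   with a conformer, or an SDF file path.
#' @param config an `fg_config`.
#' @return an `fg_run` report: list with `final` (filtered, deduplicated,
#'   scored candidate tibble), `all` (every scored candidate), `probes`,
#'   `iterations` (per-iteration tallies), `pocket`, `hotspots`, `config`.
#' @export
run_generation <- function(protein, reference, config) {
  stopifnot(inherits(config, "fg_config"))
  vmsg <- function(...) {
    if (isTRUE(getOption("fraggrow.verbose"))) {
      message(sprintf("[fraggrow %s] ", format(Sys.time(), "%H:%M:%S")), ...)
    }
  }
  if (is.character(protein)) protein <- read_protein(protein)
  if (is.character(reference)) {
    reference <- parse_molecule(paste(readLines(reference, warn = FALSE), collapse = "\n"),
                                format = "sdf")
  }
  pocket <- extract_pocket(protein, reference, cutoff = config$pocket_cutoff)
  hotspots <- detect_hotspots(pocket)
  if (!nrow(hotspots)) stop("no hotspots detected; cannot place probes")

  # --- non-iterative stage: probe placement ------------------------------
  probe_rows <- list()
  for (pi in seq_along(config$probes)) {
    pr <- config$probes[[pi]]
    placements <- tryCatch(
      enumerate_probe_placements(pr$mol, pocket, hotspots, config$model,
                                 n_conformers = config$n_probe_conformers,
                                 seed = derive_seed(config$seed, "probe", pr$id)),
      error = function(e) NULL)
    if (is.null(placements) || !nrow(placements)) next
    placements <- utils::head(placements, 32L)  # refinement budget per probe
    for (q in seq_len(nrow(placements))) {
      ref <- config$refiner$refine(placements$mol[[q]], placements$pose[[q]],
                                   pocket, hotspots, config$model)
      placements$pose[[q]] <- ref$xyz
      placements$binding_energy[q] <- ref$energy
      ph <- pharmacophore_score(placements$mol[[q]], ref$xyz, hotspots, config$model)
      placements$pharmacophore_score[q] <- ph$score
      placements$matched[[q]] <- ph$matched
    }
    placements$probe_id <- pr$id
    probe_rows[[length(probe_rows) + 1L]] <- placements
  }
  if (!length(probe_rows)) stop("zero placed probes: no probe produced a feasible pose")
  vmsg("placement done: ", sum(vapply(probe_rows, nrow, integer(1))), " poses")
  pool <- dplyr::bind_rows(probe_rows)
  sel <- select_probes(pool, k = config$k_probes, per_molecule = TRUE)
  # pool of alternative placements per probe molecule: children assembled on
  # a probe are tried on every placement of that probe, and the full-
  # molecule energy decides which site carries the growth
  pool$smiles <- vapply(pool$mol, canonical_smiles, character(1))
  pose_pool <- new.env(parent = emptyenv())
  for (smi in unique(pool$smiles)) {
    sub <- pool[pool$smiles == smi, , drop = FALSE]
    pose_pool[[smi]] <- utils::head(sub$pose, 24L)
  }
  probes <- tibble::tibble(
    id = paste0("p", seq_len(nrow(sel))),
    smiles = vapply(sel$mol, canonical_smiles, character(1)),
    mol = sel$mol, iteration = 0L, rule = "probe",
    parents = rep(list(character()), nrow(sel)),
    fragment_id = sel$probe_id, detail = "",
    pose = sel$pose,
    binding_energy = sel$binding_energy,
    pli_score = NA_real_, shape_similarity = NA_real_,
    clash = FALSE, ifp = vector("list", nrow(sel))
  )
  for (i in seq_len(nrow(probes))) {
    probes$pli_score[i] <- pli_score(probes$mol[[i]], probes$pose[[i]],
                                     pocket, hotspots, config$model)
    probes$ifp[[i]] <- compute_ifp(probes$mol[[i]], probes$pose[[i]],
                                   pocket, hotspots, config$model)
  }

  # --- iterative growth --------------------------------------------------
  frag_cache <- new.env(parent = emptyenv())
  parents <- probes
  all_scored <- list()
  tallies <- list()
  for (it in seq_len(config$max_iterations)) {
    parents <- parents[vapply(parents$mol, molecular_weight, numeric(1)) < config$mw_ceiling, ]
    if (!nrow(parents)) {
      tallies[[length(tallies) + 1L]] <- tibble::tibble(
        iteration = it, attempted = 0L, sanitize_rejected = 0L, duplicates = 0L,
        unique_products = 0L, filter_rejected = 0L, mw_rejected = 0L,
        score_failed = 0L, scored = 0L, selected = 0L,
        note = "stopped: all parents above MW ceiling")
      warning("growth stopped at iteration ", it, ": all parents above the MW ceiling")
      break
    }
    pair_context <- NULL
    if (it == 1L && nrow(parents) >= 2) {
      combs <- utils::combn(seq_len(nrow(parents)), 2)
      ok <- apply(combs, 2, function(idx) {
        c1 <- colMeans(parents$pose[[idx[1]]]); c2 <- colMeans(parents$pose[[idx[2]]])
        d <- sqrt(sum((c1 - c2)^2))
        d >= 3 && d <= config$linker_max_dist
      })
      if (any(ok)) {
        pair_context <- tibble::tibble(id_a = parents$id[combs[1, ok]],
                                       id_b = parents$id[combs[2, ok]])
      }
    }
    vmsg("iteration ", it, ": growing from ", nrow(parents), " parents")
    kids <- grow(parents, config$library, rules = config$rules,
                 pair_context = pair_context)
    tl <- attr(kids, "tally")
    vmsg("iteration ", it, ": ", nrow(kids), " unique products")
    mcf <- vapply(kids$mol, function(m) apply_mcf(m, config$filter_rules, "core")$passed,
                  logical(1))
    n_filter <- sum(!mcf)
    kids <- kids[mcf, , drop = FALSE]
    mw_ok <- vapply(kids$mol, molecular_weight, numeric(1)) <= config$mw_ceiling
    n_mw <- sum(!mw_ok)
    kids <- kids[mw_ok, , drop = FALSE]
    scored <- list()
    n_fail <- 0L
    parent_lookup <- dplyr::bind_rows(probes, dplyr::bind_rows(all_scored))
    for (q in seq_len(nrow(kids))) {
      pr_ids <- kids$parents[[q]]
      prows <- parent_lookup[match(pr_ids, parent_lookup$id), , drop = FALSE]
      alt_poses <- list()
      if (length(pr_ids) == 1) {
        alt_poses <- pose_pool[[prows$smiles[1]]] %||% list()
      }
      if (q %% 25 == 0) vmsg("iteration ", it, ": scored ", q, "/", nrow(kids))
      sc <- .score_candidate(kids[q, ], prows, pocket, hotspots, config, frag_cache,
                             alt_poses = alt_poses)
      if (is.null(sc)) { n_fail <- n_fail + 1L; next }
      row <- kids[q, ]
      row$pose <- list(sc$pose)
      row$binding_energy <- sc$binding_energy
      row$pli_score <- sc$pli_score
      row$shape_similarity <- NA_real_
      row$clash <- sc$clash
      row$ifp <- list(sc$ifp)
      scored[[length(scored) + 1L]] <- row
    }
    scored_tbl <- if (length(scored)) dplyr::bind_rows(scored) else kids[0, ]
    # two-tier docking: the strongest candidates get a second, generous
    # docking pass (more starts, more iterations) so near-native poses are
    # not lost to a tight local-search budget
    if (nrow(scored_tbl) > 0 && config$polish_top > 0) {
      ordp <- order(scored_tbl$binding_energy)
      hi_cfg <- config
      hi_cfg$dock_top <- 2L
      hi_cfg$dock_maxit <- config$polish_maxit
      for (q in utils::head(ordp, config$polish_top)) {
        pr_ids <- scored_tbl$parents[[q]]
        prows <- parent_lookup[match(pr_ids, parent_lookup$id), , drop = FALSE]
        alt_poses <- if (length(pr_ids) == 1) pose_pool[[prows$smiles[1]]] %||% list() else list()
        sc <- .score_candidate(scored_tbl[q, ], prows, pocket, hotspots, hi_cfg,
                               frag_cache, alt_poses = alt_poses)
        if (!is.null(sc) && sc$binding_energy < scored_tbl$binding_energy[q]) {
          scored_tbl$pose[[q]] <- sc$pose
          scored_tbl$binding_energy[q] <- sc$binding_energy
          scored_tbl$pli_score[q] <- sc$pli_score
          scored_tbl$clash[q] <- sc$clash
          scored_tbl$ifp[[q]] <- sc$ifp
        }
      }
    }
    selected <- if (nrow(scored_tbl)) {
      select_candidates(scored_tbl, objective = config$objective,
                        mode = config$selection_mode, k = config$k,
                        threshold = config$ifp_threshold)
    } else scored_tbl
    tallies[[length(tallies) + 1L]] <- tibble::tibble(
      iteration = it,
      attempted = sum(tl$generated), sanitize_rejected = sum(tl$rejected),
      duplicates = tl$duplicates,
      unique_products = n_filter + n_mw + n_fail + nrow(scored_tbl),
      filter_rejected = n_filter, mw_rejected = n_mw,
      score_failed = n_fail, scored = nrow(scored_tbl),
      selected = nrow(selected), note = "")
    if (nrow(scored_tbl)) all_scored[[length(all_scored) + 1L]] <- scored_tbl
    if (!nrow(selected)) {
      warning("no survivors at iteration ", it, "; stopping early")
      break
    }
    parents <- selected
    for (smi in unique(selected$smiles)) {
      pose_pool[[smi]] <- selected$pose[selected$smiles == smi]
    }
  }

  # --- final output ------------------------------------------------------
  final <- dplyr::bind_rows(probes, dplyr::bind_rows(all_scored))
  keep <- vapply(final$mol, function(m) apply_mcf(m, config$filter_rules, "enhanced")$passed,
                 logical(1))
  final <- final[keep, , drop = FALSE]
  if (nrow(final)) {
    # dedup by canonical string, keeping the best objective value
    ordv <- if (config$objective == "binding_energy") final$binding_energy else -final$pli_score
    final <- final[order(ordv, final$smiles), , drop = FALSE]
    final <- final[!duplicated(final$smiles), , drop = FALSE]
    for (i in seq_len(nrow(final))) {
      final$shape_similarity[i] <- shape_similarity(
        final$mol[[i]], final$pose[[i]], reference, reference$conformers[[1]])
    }
  } else {
    warning("no structure passed the enhanced filter; final output is empty")
  }
  structure(list(
    final = final,
    all = dplyr::bind_rows(all_scored),
    probes = probes,
    iterations = if (length(tallies)) dplyr::bind_rows(tallies) else
      tibble::tibble(iteration = integer()),
    pocket = pocket, hotspots = hotspots, config = config
  ), class = "fg_run")
}

#' @export
print.fg_run <- function(x, ...) {
  cat(sprintf("<generation run: %d probes, %d scored, %d final structures>\n",
              nrow(x$probes), nrow(x$all), nrow(x$final)))
  if (nrow(x$iterations)) print(x$iterations)
  invisible(x)
}

# Minimum pocket-frame RMSD between poses of two copies of the same
# chemical structure with possibly different atom numbering: minimized over
# all color-respecting graph isomorphisms (which subsumes automorphism
# symmetry).
cross_mol_rmsd <- function(mol_a, xyz_a, mol_b, xyz_b) {
  ga <- heavy_graph(mol_a); gb <- heavy_graph(mol_b)
  subdivide <- function(g) {
    nv <- igraph::vcount(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    ne <- nrow(el)
    g2 <- igraph::make_empty_graph(nv + ne, directed = FALSE)
    if (ne) {
      g2 <- igraph::add_edges(g2, t(rbind(cbind(el[, 1], nv + seq_len(ne)),
                                          cbind(el[, 2], nv + seq_len(ne)))))
    }
    list(g = g2, nv = nv,
         labels = c(igraph::V(g)$color_label, paste0("bond", igraph::E(g)$order)))
  }
  sa <- subdivide(ga); sb <- subdivide(gb)
  all_labels <- unique(c(sa$labels, sb$labels))
  maps <- igraph::isomorphisms(sa$g, sb$g, method = "vf2",
                               vertex.color1 = match(sa$labels, all_labels),
                               vertex.color2 = match(sb$labels, all_labels))
  if (!length(maps)) return(Inf)
  ha <- heavy_atoms(mol_a); hb <- heavy_atoms(mol_b)
  A <- xyz_a[ha, , drop = FALSE]; B <- xyz_b[hb, , drop = FALSE]
  best <- Inf
  for (m in maps) {
    # igraph returns the matched graph-1 vertex for every graph-2 vertex;
    # invert to get the candidate atom paired with each reference atom
    q <- as.integer(m)[seq_len(sa$nv)]
    perm <- integer(sa$nv)
    perm[q] <- seq_len(sa$nv)
    val <- rmsd(A, B[perm, , drop = FALSE])
    if (val < best) best <- val
  }
  best
}

#' Run the regrow-and-reproduce benchmark
#'
#' For each complex the reference ligand is fragmented; the fragments whose
#' crystal geometry forms at least one hydrogen bond with the protein
#' (same geometric windows as the energy model) become probes, all
#' fragments become building blocks, and a generation run attempts to
#' regrow the ligand in its own pocket. Reported per complex: the minimum
#' pocket-frame symmetry RMSD between a regrown copy of the ligand (or the
#' best-scoring candidate when exact regrowth is absent) and the crystal
#' pose, its classification, the ligand heavy-atom count and rotatable-bond
#' count.
#'
#' @param complexes list of `fg_toy` objects, or lists with elements
#'   `protein` (`fg_protein`) and `ligand` (molecule with crystal conformer).
#' @param config an `fg_config`; its `probes`/`library` entries are replaced
#'   per complex (extra library entries are kept as decoys).
#' @param rules linking rules enabled during regrowth. The default is the
#'   inverse of the fragmentation operator (direct bonds and linkers):
#'   fragmentation only cleaves acyclic single bonds, so fusion and spiro
#'   products can never reproduce the target and only widen the search.
#' @return an `fg_benchmark` tibble: one row per complex.
#' @export
run_benchmark <- function(complexes, config, rules = c("direct", "linker")) {
  rows <- list()
  for (ci in seq_along(complexes)) {
    cx <- complexes[[ci]]
    protein <- cx$protein
    ligand <- cx$ligand
    frags <- if (!is.null(cx$fragments)) cx$fragments else fragment_ligand(ligand)
    pocket <- extract_pocket(protein, ligand, cutoff = config$pocket_cutoff)
    hotspots <- detect_hotspots(pocket)
    xyz <- ligand$conformers[[1]]
    feats <- ligand_features(ligand, xyz)
    ct <- contact_table(feats, hotspots, config$model)
    hb_feats <- feats$atom[ct$feature[ct$kind %in% c("hb_donor", "hb_acceptor")]]
    is_probe <- vapply(frags, function(f) any(hb_feats %in% f$src_atoms), logical(1))
    if (!any(is_probe)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        complex = ci, smiles = canonical_smiles(ligand), skipped = TRUE,
        found_exact = FALSE, rmsd = NA_real_, class = NA_character_,
        heavy_atoms = length(heavy_atoms(ligand)),
        rotatable_bonds = count_rotatable_bonds(ligand))
      warning("complex ", ci, " skipped: no fragment forms a hydrogen bond")
      next
    }
    cfg <- config
    cfg$rules <- rules
    cfg$probes <- lapply(which(is_probe), function(i) {
      f <- frags[[i]]; f$role <- "probe"; f
    })
    cfg$library <- c(frags, config$library)
    cfg$seed <- derive_seed(config$seed, "benchmark", ci)
    run <- run_generation(protein, ligand, cfg)
    target <- canonical_smiles(ligand)
    cands <- dplyr::bind_rows(run$all, run$final)
    hit <- cands[cands$smiles == target, , drop = FALSE]
    found <- nrow(hit) > 0
    if (found) {
      rmsds <- vapply(seq_len(nrow(hit)), function(q) {
        cross_mol_rmsd(ligand, xyz, hit$mol[[q]], hit$pose[[q]])
      }, numeric(1))
      best_rmsd <- min(rmsds)
    } else if (nrow(run$final)) {
      best <- run$final[1, ]
      best_rmsd <- tryCatch(cross_mol_rmsd(ligand, xyz, best$mol[[1]], best$pose[[1]]),
                            error = function(e) Inf)
      if (!is.finite(best_rmsd)) best_rmsd <- NA_real_
    } else {
      best_rmsd <- NA_real_
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      complex = ci, smiles = target, skipped = FALSE, found_exact = found,
      rmsd = best_rmsd,
      class = if (is.na(best_rmsd)) NA_character_ else classify_reproduction(best_rmsd),
      heavy_atoms = length(heavy_atoms(ligand)),
      rotatable_bonds = count_rotatable_bonds(ligand))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fg_benchmark", class(out))
  out
}
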