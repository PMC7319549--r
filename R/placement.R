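# The hydration engine. Templates are visited in rank order; within a
# template, candidate waters are assessed in increasing source B-factor.
# Each candidate must pass the local-superposition RMSD gate and a strict
# clash filter (< 2.4 A to any query heavy atom or already placed water).
# The conserved sodium, when requested, is placed first under its own
# exclusion rules (no water within 2.1 A and no protein atom within 1.8 A).

#' Placement configuration
#'
#' All tunable thresholds of the hydration pipeline in one object. Defaults
#' are the standard operating values: 2.4 A clash cutoff, 2.1 A / 1.8 A
#' sodium exclusion radii (water / protein), 10 A local-fit radius with a
#' 2.0 A RMSD gate, BLOSUM62 11/1 scoring with gapped Karlin-Altschul
#' constants.
#'
#' @param clash_cutoff Water clash cutoff in Angstrom (strict `<`).
#' @param na_water,na_protein Sodium exclusion distances (Angstrom).
#' @param score_min Minimum template bit score (0 = no restriction).
#' @param query_state `"active"`, `"inactive"` or `"unknown"`.
#' @param add_sodium Attempt to place the conserved sodium first.
#' @param query_chain Query chain; default first protein chain.
#' @param local_radius,local_rmsd_max Local refinement parameters.
#' @param external_merge_cutoff Non-overlap cutoff for merging externally
#'   predicted waters.
#' @param outlier_sigma,max_cycles Global-fit outlier rejection.
#' @param state_priority `"template"` or `"tiebreak"` (see
#'   [rank_templates()]).
#' @param gate_only Use the local fit only as a gate, mapping accepted
#'   waters by the global transform.
#' @param scoring,gap_open,gap_extend,lambda,K Alignment parameters.
#' @return A `placement_config` list.
#' @export
placement_config <- function(clash_cutoff = 2.4, na_water = 2.1,
                             na_protein = 1.8, score_min = 0,
                             query_state = "unknown", add_sodium = FALSE,
                             query_chain = NULL, local_radius = 10,
                             local_rmsd_max = 2.0,
                             external_merge_cutoff = 2.4,
                             outlier_sigma = 2, max_cycles = 5,
                             state_priority = "template", gate_only = FALSE,
                             scoring = "BLOSUM62", gap_open = 11,
                             gap_extend = 1, lambda = 0.267, K = 0.041) {
  if (any(c(clash_cutoff, na_water, na_protein, local_radius,
            local_rmsd_max, external_merge_cutoff) <= 0))
    stop("all distance thresholds must be positive")
  structure(list(clash_cutoff = clash_cutoff, na_water = na_water,
                 na_protein = na_protein, score_min = score_min,
                 query_state = query_state, add_sodium = add_sodium,
                 query_chain = query_chain, local_radius = local_radius,
                 local_rmsd_max = local_rmsd_max,
                 external_merge_cutoff = external_merge_cutoff,
                 outlier_sigma = outlier_sigma, max_cycles = max_cycles,
                 state_priority = state_priority, gate_only = gate_only,
                 scoring = scoring, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "placement_config")
}

#' Clash test against occupied space
#'
#' @param position Length-3 candidate position.
#' @param occupied Numeric matrix (n x 3) of heavy-atom positions (may have
#'   zero rows).
#' @param cutoff Distance cutoff in Angstrom.
#' @return `TRUE` iff any occupied point lies strictly closer than
#'   `cutoff`; a contact at exactly `cutoff` is not a clash.
#' @export
check_clash <- function(position, occupied, cutoff = 2.4) {
  stopifnot(cutoff > 0)
  if (is.null(occupied) || !NROW(occupied)) return(FALSE)
  occupied <- matrix(as.numeric(occupied), ncol = 3)
  d2 <- (occupied[, 1] - position[1])^2 + (occupied[, 2] - position[2])^2 +
    (occupied[, 3] - position[3])^2
  min(d2) < cutoff^2
}

.prepare_ranked <- function(query, db, cfg) {
  prot <- protein_atoms(query)
  if (!nrow(prot)) stop("query has no protein chain")
  chain <- if (is.null(cfg$query_chain)) prot$chain[1] else cfg$query_chain
  qseq <- extract_sequence(query, chain)
  ranked <- rank_templates(db, qseq, query_state = cfg$query_state,
                           score_min = cfg$score_min,
                           state_priority = cfg$state_priority,
                           scoring = cfg$scoring, gap_open = cfg$gap_open,
                           gap_extend = cfg$gap_extend, lambda = cfg$lambda,
                           K = cfg$K)
  list(chain = chain, qseq = qseq, ranked = ranked)
}

.global_fits <- function(query, ranked, chain, qseq, cfg) {
  lapply(ranked, function(rt) {
    pairs <- residue_pairs(rt$alignment, attr(qseq, "resno"), rt$template)
    fit <- global_fit(query, rt$template, pairs, chain,
                      outlier_cycles = cfg$max_cycles,
                      outlier_sigma = cfg$outlier_sigma)
    list(pairs = pairs, fit = fit)
  })
}

#' Place the conserved sodium ion
#'
#' The candidate is the near-2.50 sodium of the template with the highest
#' percent identity (ties broken by best resolution), mapped by that
#' template's global transform. It is placed only when no water lies within
#' `na_water` (2.1 A) and no protein heavy atom within `na_protein`
#' (1.8 A).
#'
#' @param query An `aquahom_structure`.
#' @param ranked Output of [rank_templates()].
#' @param cfg A [placement_config()]; `existing_waters` positions are taken
#'   from the query plus `extra_waters`.
#' @param fits Optional pre-computed global fits (internal use).
#' @param extra_waters Optional matrix of additional water positions to
#'   respect.
#' @return List with `placed` (logical), `position`, `source_entry`,
#'   `reason` when not placed.
#' @export
place_sodium <- function(query, ranked, cfg = placement_config(),
                         fits = NULL, extra_waters = NULL) {
  has_ion <- vapply(ranked, function(rt)
    nrow(rt$template$ions) > 0 && any(rt$template$ions$near_250), TRUE)
  if (!any(has_ion))
    return(list(placed = FALSE, reason = "no_near_250_ion_in_templates"))
  idx <- which(has_ion)
  pid <- vapply(ranked[idx], function(rt) rt$alignment$pct_identity, 0)
  res <- vapply(ranked[idx], function(rt)
    ifelse(is.na(rt$template$resolution), Inf, rt$template$resolution), 0)
  pick <- idx[order(-pid, res)[1]]
  rt <- ranked[[pick]]
  if (is.null(fits)) {
    chain <- if (is.null(cfg$query_chain)) protein_atoms(query)$chain[1]
             else cfg$query_chain
    qseq <- extract_sequence(query, chain)
    fits <- setNames(vector("list", length(ranked)), NULL)
    fits[[pick]] <- .global_fits(query, ranked[pick], chain, qseq, cfg)[[1]]
  }
  gf <- fits[[pick]]$fit
  if (is.null(gf) || inherits(gf, "fit_skip"))
    return(list(placed = FALSE, reason = "insufficient_correspondence",
                source_entry = rt$template$entry_id))
  ion <- rt$template$ions[rt$template$ions$near_250, , drop = FALSE][1, ]
  pos <- apply_transform(as.numeric(ion[c("x", "y", "z")]), gf)
  prot_lig <- rbind(.coords(protein_atoms(query)),
                    .coords(hetero_atoms(query)))
  waters <- rbind(.coords(water_oxygens(query)),
                  if (!is.null(extra_waters)) matrix(extra_waters, ncol = 3))
  if (check_clash(pos, waters, cfg$na_water))
    return(list(placed = FALSE, reason = "water_within_2.1",
                source_entry = rt$template$entry_id, position = pos))
  if (check_clash(pos, prot_lig, cfg$na_protein))
    return(list(placed = FALSE, reason = "protein_within_1.8",
                source_entry = rt$template$entry_id, position = pos))
  list(placed = TRUE, position = pos, source_entry = rt$template$entry_id,
       source_chain = rt$template$chain_id)
}

.free_chain <- function(model) {
  used <- unique(model$atoms$chain)
  cand <- c("W", "V", "U", setdiff(LETTERS, used), letters, as.character(0:9))
  cand <- setdiff(cand, used)
  if (!length(cand)) "W" else cand[1]
}

.append_waters <- function(model, positions, bfactors, chain) {
  n <- NROW(positions)
  if (!n) return(model)
  positions <- matrix(positions, ncol = 3)
  add <- data.frame(type = "HETATM",
                    eleno = max(model$atoms$eleno, 0) + seq_len(n),
                    elety = "O", resid = "HOH", chain = chain,
                    resno = seq_len(n), insert = "",
                    x = positions[, 1], y = positions[, 2], z = positions[, 3],
                    o = 1, b = bfactors, elesy = "O")
  model$atoms <- rbind(model$atoms, add)
  model
}

#' Hydrate a query structure from the reference database
#'
#' The main pipeline: templates are ranked (state priority, bit score,
#' resolution), globally superposed onto the query with outlier rejection,
#' and their internal waters assessed in increasing source B-factor. Each
#' candidate is locally refined (10 A backbone fit, RMSD <= 2.0 A gate) and
#' accepted only when it clears every query heavy atom, every previously
#' placed water, and the sodium ion by the clash cutoff. Placed waters are
#' appended to the model as HETATM HOH on a dedicated chain, with full
#' provenance in the report. The run is deterministic.
#'
#' @param query An `aquahom_structure` (may already contain ligands and
#'   waters; these are preserved and treated as occupied space).
#' @param db A `reference_db`.
#' @param cfg A [placement_config()].
#' @return List with `model` (hydrated `aquahom_structure`) and `report`, a
#'   `placement_report`: `candidates` (one row per assessed water with
#'   status/reason/provenance), `placed`, `sodium`, `templates_used`, and
#'   the effective `config`.
#' @export
place_waters <- function(query, db, cfg = placement_config()) {
  stopifnot(inherits(db, "reference_db"))
  prep <- .prepare_ranked(query, db, cfg)
  ranked <- prep$ranked
  empty_report <- function(reason) {
    structure(list(candidates = .empty_candidates(), placed = .empty_candidates(),
                   sodium = NULL,
                   templates_used = data.frame(entry_id = character(0),
                                               chain_id = character(0),
                                               rank = integer(0),
                                               score_bits = numeric(0),
                                               pct_identity = numeric(0),
                                               n_candidates = integer(0),
                                               n_placed = integer(0),
                                               note = character(0)),
                   config = cfg, note = reason),
              class = "placement_report")
  }
  if (!length(ranked))
    return(list(model = query, report = empty_report(attr(ranked, "reason"))))

  fits <- .global_fits(query, ranked, prep$chain, prep$qseq, cfg)

  sodium <- NULL
  ion_pos <- NULL
  if (isTRUE(cfg$add_sodium)) {
    sodium <- place_sodium(query, ranked, cfg, fits = fits)
    if (isTRUE(sodium$placed)) ion_pos <- matrix(sodium$position, nrow = 1)
  }

  occupied <- heavy_atom_coords(query)
  placed_pos <- matrix(numeric(0), ncol = 3)
  rows <- list()
  tmpl_rows <- list()
  order_index <- 0L

  for (k in seq_along(ranked)) {
    rt <- ranked[[k]]
    tpl <- rt$template
    gf <- fits[[k]]$fit
    wat <- tpl$waters
    n_placed_tpl <- 0L
    if (is.null(gf) || inherits(gf, "fit_skip")) {
      if (nrow(wat)) {
        ordw <- order(wat$b)
        for (i in ordw)
          rows[[length(rows) + 1L]] <- data.frame(
            source_entry = tpl$entry_id, source_chain = tpl$chain_id,
            source_bfactor = wat$b[i], local_rmsd = NA_real_,
            x = NA_real_, y = NA_real_, z = NA_real_,
            status = "rejected", reason = "insufficient_correspondence",
            order_index = NA_integer_)
      }
      tmpl_rows[[length(tmpl_rows) + 1L]] <- data.frame(
        entry_id = tpl$entry_id, chain_id = tpl$chain_id, rank = rt$rank,
        score_bits = rt$alignment$score_bits,
        pct_identity = rt$alignment$pct_identity,
        n_candidates = nrow(wat), n_placed = 0L,
        note = "insufficient_correspondence")
      next
    }
    if (nrow(wat)) {
      ordw <- order(wat$b)  # ties keep source record order (stable)
      for (i in ordw) {
        wxyz <- as.numeric(wat[i, c("x", "y", "z")])
        ref <- local_refine_water(wxyz, tpl, query, fits[[k]]$pairs,
                                  prep$chain, radius = cfg$local_radius,
                                  rmsd_max = cfg$local_rmsd_max,
                                  global_tf = gf, gate_only = cfg$gate_only)
        if (!isTRUE(ref$accepted)) {
          rows[[length(rows) + 1L]] <- data.frame(
            source_entry = tpl$entry_id, source_chain = tpl$chain_id,
            source_bfactor = wat$b[i],
            local_rmsd = if (!is.null(ref$fit)) ref$fit$rmsd else NA_real_,
            x = NA_real_, y = NA_real_, z = NA_real_,
            status = "rejected", reason = ref$reason,
            order_index = NA_integer_)
          next
        }
        pos <- ref$position
        occ_all <- rbind(occupied, placed_pos, ion_pos)
        if (check_clash(pos, occ_all, cfg$clash_cutoff)) {
          clash_w <- check_clash(pos, rbind(placed_pos,
                                            .coords(water_oxygens(query))),
                                 cfg$clash_cutoff)
          rows[[length(rows) + 1L]] <- data.frame(
            source_entry = tpl$entry_id, source_chain = tpl$chain_id,
            source_bfactor = wat$b[i], local_rmsd = ref$fit$rmsd,
            x = pos[1], y = pos[2], z = pos[3],
            status = "rejected",
            reason = if (clash_w) "clash_water" else "clash_protein",
            order_index = NA_integer_)
          next
        }
        order_index <- order_index + 1L
        n_placed_tpl <- n_placed_tpl + 1L
        placed_pos <- rbind(placed_pos, pos)
        rows[[length(rows) + 1L]] <- data.frame(
          source_entry = tpl$entry_id, source_chain = tpl$chain_id,
          source_bfactor = wat$b[i], local_rmsd = ref$fit$rmsd,
          x = pos[1], y = pos[2], z = pos[3],
          status = "placed", reason = "", order_index = order_index)
      }
    }
    tmpl_rows[[length(tmpl_rows) + 1L]] <- data.frame(
      entry_id = tpl$entry_id, chain_id = tpl$chain_id, rank = rt$rank,
      score_bits = rt$alignment$score_bits,
      pct_identity = rt$alignment$pct_identity,
      n_candidates = nrow(wat), n_placed = n_placed_tpl, note = "")
  }

  candidates <- if (length(rows)) do.call(rbind, rows) else .empty_candidates()
  rownames(candidates) <- NULL
  placed <- candidates[candidates$status == "placed", , drop = FALSE]

  out <- query
  wchain <- .free_chain(query)
  if (nrow(placed))
    out <- .append_waters(out, as.matrix(placed[, c("x", "y", "z")]),
                          placed$source_bfactor, wchain)
  if (!is.null(ion_pos)) {
    ion_row <- data.frame(type = "HETATM",
                          eleno = max(out$atoms$eleno, 0) + 1L,
                          elety = "NA", resid = "NA", chain = wchain,
                          resno = nrow(placed) + 1L, insert = "",
                          x = ion_pos[1], y = ion_pos[2], z = ion_pos[3],
                          o = 1, b = 0, elesy = "NA")
    out$atoms <- rbind(out$atoms, ion_row)
  }
  report <- structure(list(candidates = candidates, placed = placed,
                           sodium = sodium,
                           templates_used = do.call(rbind, tmpl_rows),
                           config = cfg, note = ""),
                      class = "placement_report")
  list(model = out, report = report)
}

.empty_candidates <- function() {
  data.frame(source_entry = character(0), source_chain = character(0),
             source_bfactor = numeric(0), local_rmsd = numeric(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             status = character(0), reason = character(0),
             order_index = integer(0))
}

#' @export
print.placement_report <- function(x, ...) {
  cat(sprintf("<placement_report> %d placed / %d assessed",
              nrow(x$placed), nrow(x$candidates)))
  if (!is.null(x$sodium))
    cat(sprintf("; sodium %s", if (isTRUE(x$sodium$placed)) "placed"
                else paste0("not placed (", x$sodium$reason, ")")))
  if (nzchar(x$note)) cat("; ", x$note)
  cat("\n")
  invisible(x)
}

#' Write a placement report as TSV
#'
#' Columns: index, x, y, z, source_entry, source_chain, source_bfactor,
#' local_rmsd, status, reason. Header lines (prefixed `#`) echo the
#' effective thresholds.
#'
#' @param report A `placement_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_placement_report <- function(report, path) {
  cfg <- report$config
  hdr <- sprintf("# clash_cutoff=%g na_water=%g na_protein=%g score_min=%g local_radius=%g local_rmsd_max=%g state=%s",
                 cfg$clash_cutoff, cfg$na_water, cfg$na_protein,
                 cfg$score_min, cfg$local_radius, cfg$local_rmsd_max,
                 cfg$query_state)
  df <- report$candidates
  df <- data.frame(index = df$order_index, x = df$x, y = df$y, z = df$z,
                   source_entry = df$source_entry,
                   source_chain = df$source_chain,
                   source_bfactor = df$source_bfactor,
                   local_rmsd = df$local_rmsd, status = df$status,
                   reason = df$reason)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(df, digits = 15, trim = TRUE, nsmall = 0),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge externally predicted waters that do not overlap
#'
#' Adds each predicted water position (e.g. from an energy-based method)
#' iff it lies at least `cutoff` from every atom of the current model,
#' including waters already placed; the same strict-inequality clash rule
#' as [check_clash()]. Accepted predictions also occupy space for
#' subsequent ones.
#'
#' @param model A (typically hydrated) `aquahom_structure`.
#' @param predicted Matrix (n x 3) of predicted water oxygen positions, or
#'   an `aquahom_structure` / PDB path whose waters are used.
#' @param cutoff Non-overlap cutoff in Angstrom (default 2.4).
#' @return List with `model`, `n_added`, `n_rejected`, `added` (matrix of
#'   accepted positions).
#' @export
merge_external_predictions <- function(model, predicted, cutoff = 2.4) {
  if (is.character(predicted)) predicted <- read_pdb(predicted)
  if (inherits(predicted, "aquahom_structure"))
    predicted <- .coords(water_oxygens(predicted))
  predicted <- matrix(as.numeric(predicted), ncol = 3)
  occupied <- heavy_atom_coords(model)
  added <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(nrow(predicted))) {
    pos <- predicted[i, ]
    if (!check_clash(pos, rbind(occupied, added), cutoff))
      added <- rbind(added, pos)
  }
  out <- model
  if (nrow(added)) {
    chain <- .free_chain(model)
    out <- .append_waters(model, added, rep(0, nrow(added)), chain)
  }
  list(model = out, n_added = nrow(added),
       n_rejected = nrow(predicted) - nrow(added), added = added)
}
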