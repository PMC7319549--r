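# Recovery benchmark: how many of a structure's own internal waters does
# the pipeline reproduce once that structure's entry is removed from the
# reference database? A placed water "recovers" an original when it lies
# within the cutoff (default 2 A), under a one-to-one matching.

#' Water recovery between original and placed sets
#'
#' Builds a one-to-one matching greedily over all (original, placed) pairs
#' in ascending distance, accepting a pair iff its distance is strictly
#' below `cutoff` and neither member is already matched. At small n this
#' greedy matching coincides with the optimal bipartite matching (checked
#' exhaustively in the test suite).
#'
#' @param original Matrix (m x 3) of reference internal water positions;
#'   must be non-empty.
#' @param placed Matrix (n x 3) of placed water positions (may be empty).
#' @param cutoff Match cutoff in Angstrom (default 2.0, strict `<`).
#' @return A `recovery_result`: `n_original`, `n_recovered`,
#'   `pct_recovery`, `mean_distance` (over matched pairs; 0 with
#'   `no_matches = TRUE` when none), `matches` (data frame `original`,
#'   `placed`, `distance`).
#' @export
water_recovery <- function(original, placed, cutoff = 2.0) {
  stopifnot(cutoff > 0)
  original <- matrix(as.numeric(original), ncol = 3)
  if (!nrow(original)) stop("no original waters: nothing to recover")
  placed <- if (is.null(placed)) matrix(numeric(0), ncol = 3)
            else matrix(as.numeric(placed), ncol = 3)
  matches <- data.frame(original = integer(0), placed = integer(0),
                        distance = numeric(0))
  if (nrow(placed)) {
    d <- outer(seq_len(nrow(original)), seq_len(nrow(placed)),
               Vectorize(function(i, j) sqrt(sum((original[i, ] - placed[j, ])^2))))
    ord <- order(d)
    used_o <- logical(nrow(original)); used_p <- logical(nrow(placed))
    for (k in ord) {
      if (d[k] >= cutoff) break
      i <- (k - 1) %% nrow(original) + 1
      j <- (k - 1) %/% nrow(original) + 1
      if (used_o[i] || used_p[j]) next
      used_o[i] <- TRUE; used_p[j] <- TRUE
      matches <- rbind(matches, data.frame(original = i, placed = j,
                                           distance = d[k]))
    }
  }
  n_rec <- nrow(matches)
  structure(list(n_original = nrow(original), n_recovered = n_rec,
                 pct_recovery = 100 * n_rec / nrow(original),
                 mean_distance = if (n_rec) mean(matches$distance) else 0,
                 no_matches = n_rec == 0, matches = matches),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> %d/%d recovered (%.1f%%), mean distance %.3f A\n",
              x$n_recovered, x$n_original, x$pct_recovery, x$mean_distance))
  invisible(x)
}

#' Select benchmark entries from a reference database
#'
#' The benchmark admits entries with resolution strictly below
#' `max_resolution` and strictly more than `min_waters` internal waters.
#'
#' @param db A `reference_db`.
#' @param max_resolution Resolution bound in Angstrom (default 2.8).
#' @param min_waters Internal-water count bound (default 5).
#' @return Character vector of admitted entry ids.
#' @export
select_test_entries <- function(db, max_resolution = 2.8, min_waters = 5) {
  ok <- vapply(db$entries, function(e)
    !is.na(e$resolution) && e$resolution < max_resolution &&
      nrow(e$waters) > min_waters, TRUE)
  vapply(db$entries[ok], function(e) e$entry_id, "")
}

.entry_to_query <- function(entry) {
  bb <- entry$backbone
  atoms <- data.frame(type = "ATOM", eleno = seq_len(nrow(bb)),
                      elety = bb$elety, resid = bb$resid,
                      chain = entry$chain_id, resno = bb$resno, insert = "",
                      x = bb$x, y = bb$y, z = bb$z, o = 1, b = 0,
                      elesy = toupper(substr(bb$elety, 1, 1)))
  structure_model(atoms, entry_id = entry$entry_id,
                  resolution = entry$resolution)
}

#' Leave-one-out water-recovery benchmark
#'
#' For each test entry, its stored backbone (waters stripped) becomes the
#' query, every database entry sharing its `entry_id` is excluded (whole
#' entry, not just its waters, so identical coordinates cannot leak back),
#' the query is hydrated, and recovery against the held-out internal
#' waters is computed.
#'
#' @param db A `reference_db`.
#' @param test_entries Character vector of entry ids present in `db` (see
#'   [select_test_entries()]).
#' @param cfg A [placement_config()].
#' @param cutoff Recovery cutoff in Angstrom (default 2.0).
#' @return Data frame with one row per test entry: `entry`, `n_original`,
#'   `n_recovered`, `pct_recovery`, `mean_distance`, `n_placed`.
#' @export
leave_one_out <- function(db, test_entries, cfg = placement_config(),
                          cutoff = 2.0) {
  ids <- vapply(db$entries, function(e) e$entry_id, "")
  missing <- setdiff(test_entries, ids)
  if (length(missing))
    stop("test entries not in database: ", paste(missing, collapse = ", "))
  rows <- lapply(test_entries, function(id) {
    entry <- db$entries[[match(id, ids)]]
    query <- .entry_to_query(entry)
    view <- reference_db(db$entries[ids != id], provenance = db$provenance)
    res <- place_waters(query, view, cfg)
    placed <- if (nrow(res$report$placed))
      as.matrix(res$report$placed[, c("x", "y", "z")])
    else matrix(numeric(0), ncol = 3)
    if (!nrow(entry$waters))
      return(data.frame(entry = id, n_original = 0L, n_recovered = 0L,
                        pct_recovery = NA_real_, mean_distance = NA_real_,
                        n_placed = nrow(placed)))
    rec <- water_recovery(as.matrix(entry$waters[, c("x", "y", "z")]),
                          placed, cutoff)
    data.frame(entry = id, n_original = rec$n_original,
               n_recovered = rec$n_recovered,
               pct_recovery = rec$pct_recovery,
               mean_distance = rec$mean_distance, n_placed = nrow(placed))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
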