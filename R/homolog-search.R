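# Template ranking by pairwise local sequence alignment. The engine is an
# affine-gap Smith-Waterman (Rcpp) with BLOSUM62 11/1 by default; raw
# scores are converted to bit scores with the gapped Karlin-Altschul
# constants lambda = 0.267, K = 0.041 so that familiar blastp-style bit
# thresholds (e.g. 300 for close homologs) keep their meaning.

.seq_to_idx <- function(seq, alphabet) {
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  idx - 1L
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps (a gap of length L costs
#' `gap_open + L * gap_extend`, the BLAST convention). The bit score is
#' `(lambda * S - ln K) / ln 2`. Percent identity is computed over aligned
#' (non-gap) columns.
#'
#' @param query_seq,template_seq Amino-acid strings (one-letter codes;
#'   unknown characters score as X).
#' @param scoring Substitution matrix name, see [scoring_matrix()].
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @param lambda,K Karlin-Altschul constants for the bit-score conversion.
#' @return An `alignment_result`: list with `score_raw`, `score_bits`,
#'   `pct_identity`, `n_aligned`, and `correspondence`, a data frame of
#'   1-based aligned positions (`qpos`, `tpos`), strictly increasing in
#'   both sequences.
#' @export
#' @examples
#' align_pair("HEAGAWGHEE", "PAWHEAE", scoring = "BLOSUM50",
#'            gap_open = 10, gap_extend = 1)$score_raw
align_pair <- function(query_seq, template_seq, scoring = "BLOSUM62",
                       gap_open = 11, gap_extend = 1,
                       lambda = 0.267, K = 0.041) {
  smat <- scoring_matrix(scoring)
  alphabet <- rownames(smat)
  q <- .seq_to_idx(query_seq, alphabet)
  t <- .seq_to_idx(template_seq, alphabet)
  if (!length(q) || !length(t))
    stop("empty sequence in alignment")
  if (all(strsplit(toupper(query_seq), "")[[1]] == "X") ||
      all(strsplit(toupper(template_seq), "")[[1]] == "X"))
    stop("sequence contains no standard residues")
  res <- .sw_align_cpp(q, t, smat, gap_open, gap_extend)
  bits <- (lambda * res$score - log(K)) / log(2)
  pct <- if (res$n_aligned > 0) 100 * res$n_ident / res$n_aligned else 0
  structure(list(score_raw = res$score, score_bits = bits,
                 pct_identity = pct, n_aligned = res$n_aligned,
                 correspondence = data.frame(qpos = res$qpos,
                                             tpos = res$tpos)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> raw %g, %.1f bits, %.1f%% identity over %d columns\n",
              x$score_raw, x$score_bits, x$pct_identity, x$n_aligned))
  invisible(x)
}

#' Rank reference templates against a query sequence
#'
#' Aligns the query to every template, drops templates below the bit-score
#' threshold, and orders the rest by (state match when a state is given and
#' `state_priority = "template"`, bit score descending, resolution
#' ascending, then entry id / chain for determinism). With
#' `state_priority = "tiebreak"` the state match is demoted to a tie-break
#' after the score.
#'
#' @param db A `reference_db`.
#' @param query_seq Query amino-acid string.
#' @param query_state `"active"`, `"inactive"` or `"unknown"` (no
#'   prioritisation).
#' @param score_min Minimum bit score; templates strictly below are
#'   excluded.
#' @param state_priority `"template"` (primary sort key) or `"tiebreak"`.
#' @param scoring,gap_open,gap_extend,lambda,K Passed to [align_pair()].
#' @return List of `ranked_template` objects (possibly empty, with
#'   attribute `reason = "no templates above threshold"`), each holding
#'   `template`, `alignment`, `state_match`, `rank`.
#' @export
rank_templates <- function(db, query_seq, query_state = "unknown",
                           score_min = 0, state_priority = c("template", "tiebreak"),
                           scoring = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, lambda = 0.267, K = 0.041) {
  stopifnot(inherits(db, "reference_db"))
  state_priority <- match.arg(state_priority)
  if (!length(db$entries)) stop("reference database is empty")
  cands <- lapply(db$entries, function(e) {
    al <- align_pair(query_seq, e$sequence, scoring = scoring,
                     gap_open = gap_open, gap_extend = gap_extend,
                     lambda = lambda, K = K)
    list(template = e, alignment = al,
         state_match = query_state != "unknown" && identical(e$state, query_state))
  })
  keep <- vapply(cands, function(c) c$alignment$score_bits >= score_min, TRUE)
  cands <- cands[keep]
  if (!length(cands)) {
    out <- list()
    attr(out, "reason") <- "no templates above threshold"
    return(out)
  }
  bits <- vapply(cands, function(c) c$alignment$score_bits, 0)
  match_state <- vapply(cands, function(c) c$state_match, TRUE)
  resol <- vapply(cands, function(c)
    ifelse(is.null(c$template$resolution) || is.na(c$template$resolution),
           Inf, c$template$resolution), 0)
  eid <- vapply(cands, function(c) c$template$entry_id, "")
  cid <- vapply(cands, function(c) c$template$chain_id, "")
  use_state <- query_state != "unknown" && state_priority == "template"
  ord <- order(if (use_state) !match_state else rep(FALSE, length(cands)),
               -bits,
               if (!use_state && query_state != "unknown") !match_state
               else rep(FALSE, length(cands)),
               resol, eid, cid, method = "radix")
  cands <- cands[ord]
  for (i in seq_along(cands)) {
    cands[[i]]$rank <- i
    class(cands[[i]]) <- "ranked_template"
  }
  cands
}

#' @export
print.ranked_template <- function(x, ...) {
  cat(sprintf("#%d %s/%s  %.1f bits  %.1f%% id  state_match=%s\n",
              x$rank, x$template$entry_id, x$template$chain_id,
              x$alignment$score_bits, x$alignment$pct_identity,
              x$state_match))
  invisible(x)
}
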