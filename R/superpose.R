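# Rigid-body superposition. Global fits use corresponded C-alpha atoms with
# iterative outlier rejection; each candidate water is then re-fit locally
# on the backbone atoms of residues within 10 A and only kept when the
# local RMSD stays within 2.0 A.

#' Apply a rigid transform to coordinates
#'
#' @param coords Numeric matrix (n x 3) or length-3 vector.
#' @param tf A `rigid_transform` (fields `rotation`, `translation`) or a
#'   `fit_result` from [kabsch_fit()].
#' @return Transformed coordinates, same shape as the input.
#' @export
apply_transform <- function(coords, tf) {
  if (!is.null(tf$transform)) tf <- tf$transform
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(as.numeric(coords), ncol = 3) else as.matrix(coords)
  out <- m %*% t(tf$rotation)
  out <- sweep(out, 2, tf$translation, "+")
  if (vec) as.numeric(out) else out
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `moving` and `fixed` point sets, via SVD of the cross-covariance with
#' reflection correction (det(R) = +1 always).
#'
#' @param moving,fixed Numeric matrices (n x 3), n >= 3, same n; the
#'   transform maps `moving` onto `fixed`.
#' @return A `fit_result`: list with `transform` (`rigid_transform` with
#'   `rotation`, `translation`), `rmsd`, `n_pairs`, `pairs_used` (set by
#'   [global_fit()]).
#' @export
kabsch_fit <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("point sets differ in size")
  if (nrow(moving) < 3) stop("insufficient correspondence: need >= 3 pairs")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  X <- sweep(moving, 2, cm); Y <- sweep(fixed, 2, cf)
  sv_m <- svd(X)$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1))
    stop("degenerate point set: points are collinear")
  H <- t(X) %*% Y
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cf - R %*% cm)
  fitted <- sweep(moving %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - fixed)^2)))
  structure(list(transform = structure(list(rotation = R, translation = tr),
                                       class = "rigid_transform"),
                 rmsd = rmsd, n_pairs = nrow(moving), pairs_used = NULL),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> rmsd %.4f A over %d pairs\n", x$rmsd, x$n_pairs))
  invisible(x)
}

.ca_coords <- function(backbone, resnos) {
  ca <- backbone[backbone$elety == "CA", , drop = FALSE]
  m <- ca[match(resnos, ca$resno), c("x", "y", "z"), drop = FALSE]
  as.matrix(m)
}

.query_atom_coords <- function(query, chain, resnos, elety) {
  a <- query$atoms
  sel <- a$chain == chain
  a <- a[sel, , drop = FALSE]
  key <- paste(a$resno, a$elety)
  m <- a[match(paste(resnos, elety), key), c("x", "y", "z"), drop = FALSE]
  as.matrix(m)
}

#' Global template-to-query superposition with outlier rejection
#'
#' Kabsch fit on corresponded C-alpha atoms; pairs whose residual exceeds
#' `outlier_sigma` times the current RMSD are dropped and the fit repeated,
#' up to `outlier_cycles` times or until stable, so displaced loops do not
#' distort the core fit.
#'
#' @param query An `aquahom_structure`.
#' @param template A `template_entry`.
#' @param res_pairs Data frame with columns `q_resno`, `t_resno`
#'   (corresponded residue numbers; see [residue_pairs()]).
#' @param query_chain Query chain label.
#' @param outlier_cycles Maximum rejection cycles (default 5).
#' @param outlier_sigma Residual cutoff in multiples of the RMSD (default 2).
#' @return A `fit_result` with `pairs_used`, or a `fit_skip` object (with
#'   field `reason`) when fewer than 3 usable pairs exist: the template is
#'   skipped, not an error.
#' @export
global_fit <- function(query, template, res_pairs, query_chain,
                       outlier_cycles = 5, outlier_sigma = 2) {
  t_ca <- .ca_coords(template$backbone, res_pairs$t_resno)
  q_ca <- .query_atom_coords(query, query_chain, res_pairs$q_resno,
                             rep("CA", nrow(res_pairs)))
  ok <- stats::complete.cases(t_ca) & stats::complete.cases(q_ca)
  pairs <- res_pairs[ok, , drop = FALSE]
  t_ca <- t_ca[ok, , drop = FALSE]; q_ca <- q_ca[ok, , drop = FALSE]
  if (nrow(pairs) < 3)
    return(structure(list(reason = "insufficient_correspondence",
                          n_pairs = nrow(pairs)),
                     class = "fit_skip"))
  fit <- kabsch_fit(t_ca, q_ca)
  for (cyc in seq_len(outlier_cycles)) {
    fitted <- apply_transform(t_ca, fit)
    resid <- sqrt(rowSums((fitted - q_ca)^2))
    keep <- resid <= outlier_sigma * max(fit$rmsd, 1e-12)
    if (all(keep) || sum(keep) < 3) break
    pairs <- pairs[keep, , drop = FALSE]
    t_ca <- t_ca[keep, , drop = FALSE]; q_ca <- q_ca[keep, , drop = FALSE]
    fit <- kabsch_fit(t_ca, q_ca)
  }
  fit$pairs_used <- pairs
  fit
}

#' Residue correspondence between query and template
#'
#' Converts the aligned-column pairs of an [align_pair()] result into
#' author residue numbers on both sides.
#'
#' @param alignment An `alignment_result`.
#' @param query_resno Integer vector mapping query sequence position to
#'   residue number (attribute `resno` of [extract_sequence()]).
#' @param template A `template_entry` (uses its `seq_resno`).
#' @return Data frame with columns `q_resno`, `t_resno`.
#' @export
residue_pairs <- function(alignment, query_resno, template) {
  data.frame(q_resno = query_resno[alignment$correspondence$qpos],
             t_resno = template$seq_resno[alignment$correspondence$tpos])
}

#' Local refinement of one candidate water position
#'
#' Template residues with any stored heavy atom within `radius` of the
#' water oxygen (template frame) are intersected with the residue
#' correspondence; the backbone atoms (N, CA, C, O) of those pairs are
#' superposed and, when at least 3 residue pairs are available and the
#' local RMSD is at most `rmsd_max`, the water is mapped into the query
#' frame by the local transform.
#'
#' @param water_xyz Length-3 water oxygen position in the template frame.
#' @param template A `template_entry`.
#' @param query An `aquahom_structure`.
#' @param res_pairs Residue correspondence (see [residue_pairs()]).
#' @param query_chain Query chain label.
#' @param radius Neighbourhood radius in Angstrom (default 10).
#' @param rmsd_max Local RMSD gate in Angstrom (default 2.0).
#' @param global_tf Fallback transform; only used when `gate_only = TRUE`.
#' @param gate_only If `TRUE`, the local fit is used only as a gate and the
#'   accepted water is mapped by `global_tf` instead (default `FALSE`).
#' @return List with `accepted` (logical); when accepted, `position`
#'   (length-3) and `fit`; when rejected, `reason` (`"rmsd_exceeded"` or
#'   `"insufficient_local_pairs"`).
#' @export
local_refine_water <- function(water_xyz, template, query, res_pairs,
                               query_chain, radius = 10, rmsd_max = 2.0,
                               global_tf = NULL, gate_only = FALSE) {
  bb <- template$backbone
  d2 <- (bb$x - water_xyz[1])^2 + (bb$y - water_xyz[2])^2 +
    (bb$z - water_xyz[3])^2
  near_res <- unique(bb$resno[d2 <= radius^2])
  pairs <- res_pairs[res_pairs$t_resno %in% near_res, , drop = FALSE]
  if (nrow(pairs) < 3)
    return(list(accepted = FALSE, reason = "insufficient_local_pairs",
                n_pairs = nrow(pairs)))
  tb <- bb[bb$resno %in% pairs$t_resno, , drop = FALSE]
  q_resno <- pairs$q_resno[match(tb$resno, pairs$t_resno)]
  q_xyz <- .query_atom_coords(query, query_chain, q_resno, tb$elety)
  ok <- stats::complete.cases(q_xyz)
  if (length(unique(tb$resno[ok])) < 3)
    return(list(accepted = FALSE, reason = "insufficient_local_pairs",
                n_pairs = length(unique(tb$resno[ok]))))
  t_xyz <- as.matrix(tb[ok, c("x", "y", "z")])
  q_xyz <- q_xyz[ok, , drop = FALSE]
  fit <- tryCatch(kabsch_fit(t_xyz, q_xyz), error = function(e) NULL)
  if (is.null(fit))
    return(list(accepted = FALSE, reason = "insufficient_local_pairs",
                n_pairs = length(unique(tb$resno[ok]))))
  fit$n_pairs <- length(unique(tb$resno[ok]))
  if (fit$rmsd > rmsd_max)
    return(list(accepted = FALSE, reason = "rmsd_exceeded", fit = fit))
  tfm <- if (gate_only && !is.null(global_tf)) global_tf else fit
  list(accepted = TRUE, position = apply_transform(water_xyz, tfm), fit = fit)
}
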