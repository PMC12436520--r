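#' Score detections against ground truth
#'
#' Matches detections to ground-truth positions frame by frame with greedy
#' one-to-one nearest matching within `match_radius`. Matched detections are
#' true positives; unmatched truth objects are false negatives; unmatched
#' detections are false positives. TP and FN rates are normalized by the
#' ground-truth count, the FP rate by the detection count, so
#' `tp_rate + fn_rate = 1` always holds. True negatives have no natural
#' definition in object detection and are reported as structurally zero.
#'
#' @param dets tibble with `frame`, `x_um`, `y_um` (e.g. [detect_stack()]).
#' @param truth tibble with `frame`, `x_um`, `y_um` (same frame indexing).
#' @param match_radius maximum center distance counted as a match (um).
#' @return one-row tibble: `n_gt`, `n_det`, `tp`, `fp`, `fn`, `tp_rate`,
#'   `fp_rate`, `fn_rate`, `tn_rate` (always 0).
#' @export
evaluate_detections <- function(dets, truth, match_radius = 2) {
  check_positive(match_radius, "match_radius")
  check_columns(dets, c("frame", "x_um", "y_um"), "dets")
  check_columns(truth, c("frame", "x_um", "y_um"), "truth")
  frames <- union(unique(dets$frame), unique(truth$frame))
  tp <- 0L
  for (f in frames) {
    d <- dets[dets$frame == f, , drop = FALSE]
    g <- truth[truth$frame == f, , drop = FALSE]
    if (nrow(d) == 0L || nrow(g) == 0L) next
    dist <- sqrt(outer(d$x_um, g$x_um, "-")^2 + outer(d$y_um, g$y_um, "-")^2)
    cand <- which(dist <= match_radius, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    cand <- cand[order(dist[cand]), , drop = FALSE]
    used_d <- logical(nrow(d)); used_g <- logical(nrow(g))
    for (i in seq_len(nrow(cand))) {
      di <- cand[i, 1L]; gi <- cand[i, 2L]
      if (!used_d[di] && !used_g[gi]) {
        used_d[di] <- TRUE; used_g[gi] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  n_gt <- nrow(truth); n_det <- nrow(dets)
  fn <- n_gt - tp
  fp <- n_det - tp
  tibble(
    n_gt = n_gt, n_det = n_det, tp = tp, fp = fp, fn = fn,
    tp_rate = if (n_gt > 0) tp / n_gt else NA_real_,
    fp_rate = if (n_det > 0) fp / n_det else 0,
    fn_rate = if (n_gt > 0) fn / n_gt else NA_real_,
    tn_rate = 0
  )
}
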