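#' ROC analysis over per-video TTROI values
#'
#' Builds the empirical ROC for the rule "call a video cancer iff its TTROI
#' is at least the threshold". Candidate thresholds are the unique observed
#' TTROI values plus `+Inf` (the never-positive rule); midpoints are not
#' used, which keeps the curve reproducible and is sufficient for a step
#' function. The AUC is the trapezoidal area over the (FPR, sensitivity)
#' polyline closed at (0, 0) and (1, 1); it equals the tie-corrected
#' Mann-Whitney statistic U / (n1 n2) with ties scoring one half.
#'
#' @param ttroi numeric vector of per-video TTROI values (seconds).
#' @param truth vector of ground-truth labels; `positive` marks the cancer
#'   class.
#' @param positive label of the positive class (default `"cancer"`).
#' @return list of class `roc_result`: `points` (data frame `threshold`,
#'   `sens`, `fpr`, `spec`, `youden_j`), `auc`, `best_cutoff`, `j_at_best`,
#'   `n_pos`, `n_neg`.
#' @export
roc_points <- function(ttroi, truth, positive = "cancer") {
  stopifnot(length(ttroi) == length(truth), all(is.finite(ttroi)))
  pos <- truth == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC undefined: need at least one positive and one negative truth")
  thr <- c(sort(unique(ttroi)), Inf)
  sens <- vapply(thr, function(t) mean(ttroi[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(ttroi[!pos] >= t), numeric(1))
  pts <- data.frame(threshold = thr, sens = sens, fpr = fpr,
                    spec = 1 - fpr, youden_j = sens - fpr)
  # polyline from (1,1) at the smallest threshold down to (0,0) at +Inf;
  # close at the corners in case the extremes are not attained
  xx <- c(1, fpr, 0)
  yy <- c(1, sens, 0)
  auc <- sum((xx[-length(xx)] - xx[-1]) * (yy[-length(yy)] + yy[-1]) / 2)
  j <- pts$youden_j
  best <- which(j >= max(j) - 1e-12)[1]  # ties break toward smallest threshold
  structure(
    list(points = pts, auc = auc, best_cutoff = thr[best],
         j_at_best = j[best], n_pos = n_pos, n_neg = n_neg),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f over %d thresholds (%d pos / %d neg)\n",
              x$auc, nrow(x$points), x$n_pos, x$n_neg))
  cat(sprintf("  best cutoff (Youden) %.4g s, J = %.4f\n",
              x$best_cutoff, x$j_at_best))
  invisible(x)
}

#' Youden-optimal TTROI cutoff
#'
#' Returns the candidate threshold maximising Youden's J = sensitivity +
#' specificity - 1. Ties are broken toward the smallest threshold, which
#' favours sensitivity — the desirable side for a rule-out test whose value
#' lies in a low negative likelihood ratio.
#'
#' @param roc an object from [roc_points()].
#' @return a single threshold (seconds; may be `Inf` in degenerate cases).
#' @export
best_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  roc$best_cutoff
}

#' Classify a video from its TTROI
#'
#' A video is diagnosed as cancer iff its TTROI is at least the cutoff
#' (closed inequality, so `cutoff_s = 0` calls every video cancer and the
#' smallest positive observed TTROI is itself a usable cutoff). The
#' headline operating point uses a 1-s cutoff.
#'
#' @param ttroi numeric vector of TTROI values, or a single `video_summary`.
#' @param cutoff_s non-negative cutoff in seconds (default 1).
#' @return character vector of `"cancer"` / `"non_cancer"`.
#' @export
classify_video <- function(ttroi, cutoff_s = 1.0) {
  stopifnot(is.numeric(cutoff_s), length(cutoff_s) == 1L, cutoff_s >= 0)
  if (inherits(ttroi, "video_summary")) ttroi <- ttroi$ttroi_s
  ifelse(ttroi >= cutoff_s, "cancer", "non_cancer")
}
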