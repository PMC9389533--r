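# Independent brute-force oracles used across the suite.

# Transitive-closure single-linkage clustering of cancer-tag times at a
# distance threshold: O(n^2) label propagation over the full adjacency
# matrix, deliberately independent of the linear-scan implementation.
oracle_rois <- function(times, gap) {
  tt <- sort(times)
  n <- length(tt)
  if (n == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_tags = integer(0)))
  adj <- abs(outer(tt, tt, "-")) <= gap
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), numeric(1))
    if (identical(new, comp)) break
    comp <- new
  }
  out <- do.call(rbind, lapply(unique(comp), function(k) {
    grp <- tt[comp == k]
    data.frame(start_s = min(grp), end_s = max(grp), n_tags = length(grp))
  }))
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Tie-corrected Mann-Whitney AUC by exhaustive pair counting.
oracle_auc <- function(values, truth, positive = "cancer") {
  pos <- values[truth == positive]
  neg <- values[truth != positive]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Exhaustive Youden scan over the candidate thresholds.
oracle_best_j <- function(values, truth, positive = "cancer") {
  thr <- c(sort(unique(values)), Inf)
  j <- vapply(thr, function(t) {
    mean(values[truth == positive] >= t) - mean(values[truth != positive] >= t)
  }, numeric(1))
  list(cutoff = thr[which(j >= max(j) - 1e-12)[1]], j = max(j))
}

# Random small frame_series with a mix of labels and optional duplicate
# timestamps, for property tests.
random_series <- function(n = NULL, duplicate_t = FALSE) {
  if (is.null(n)) n <- sample(1:60, 1)
  t <- sort(round(runif(n, 0, 120), 3))
  if (duplicate_t && n > 2) t[sample(n - 1, 1) + 1] <- t[sample(n - 1, 1)]
  t <- sort(t)
  labels <- sample(frame_labels(), n, replace = TRUE,
                   prob = c(0.3, 0.2, 0.3, 0.2))
  frame_series(paste0("r", sample.int(1e6, 1)),
               data.frame(t = t, label = labels), duration_s = 125)
}

cancer_times <- function(series) {
  r <- collapse_frames(series)$records
  sort(r$t[r$label == "cancer"])
}
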