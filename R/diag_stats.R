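#' Round half away from zero, report style
#'
#' Clinical reports (and the tables this package reproduces) round half
#' up: 0.625 prints as 0.63. R's `round()` rounds half to even instead
#' (0.62), so report formatting goes through this helper. Full precision
#' is always retained internally; rounding is display-only.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_report <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * trunc(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' 2x2 confusion counts from aligned truth/prediction vectors
#'
#' @param truth,prediction aligned vectors of binary labels.
#' @param positive label of the positive class (default `"cancer"`).
#' @return list of class `confusion_counts` with integer fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_counts <- function(truth, prediction, positive = "cancer") {
  if (length(truth) != length(prediction))
    stop("truth and prediction must have equal length")
  tp <- sum(truth == positive & prediction == positive)
  fp <- sum(truth != positive & prediction == positive)
  fn <- sum(truth == positive & prediction != positive)
  tn <- sum(truth != positive & prediction != positive)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The Wilson score interval (the interval `prop.test()` inverts when run
#' without continuity correction). Always inside `[0, 1]` and always
#' containing the point estimate; behaves sensibly at the boundaries, e.g.
#' 1 success of 1 gives roughly (0.21, 1.00) at the 95% level. Vectorised
#' over `x` and `n`.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf_level confidence level (default 0.95).
#' @return data frame with columns `estimate`, `lower`, `upper`.
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(all(x >= 0), all(n >= 1), all(x <= n))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(estimate = p, lower = pmax(0, centre - half),
             upper = pmin(1, centre + half))
}

#' Diagnostic accuracy metrics with confidence intervals
#'
#' From the 2x2 counts computes sensitivity TP/(TP+FN), specificity
#' TN/(FP+TN), overall accuracy, the positive likelihood ratio
#' PLR = sens/(1 - spec) and the negative likelihood ratio
#' NLR = (1 - sens)/spec. Proportions carry Wilson score intervals;
#' likelihood ratios carry the standard log-method interval
#' (exp(log LR +/- z * se), with se^2 = 1/TP - 1/(TP+FN) + 1/FP - 1/(FP+TN)
#' for the PLR and the FN/TN analogue for the NLR). A zero denominator
#' makes the corresponding LR infinite; it is reported as `Inf` with `NA`
#' interval and flagged, not raised as an error.
#'
#' @param counts a [confusion_counts()] object.
#' @param ci_level confidence level (default 0.95).
#' @return list of class `diagnostic_report` with fields `sensitivity`,
#'   `specificity`, `accuracy`, `plr`, `nlr` (each a list `estimate`,
#'   `lower`, `upper`), `n_pos`, `n_neg`, `counts`, `flags`.
#' @examples
#' diagnostic_metrics(counts_2x2(tp = 48, fp = 14, fn = 5, tn = 50))
#' @export
diagnostic_metrics <- function(counts, ci_level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  n_pos <- tp + fn
  n_neg <- fp + tn
  if (n_pos < 1 || n_neg < 1)
    stop("need at least one positive and one negative case")
  n <- n_pos + n_neg
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  as_triplet <- function(ci) list(estimate = ci$estimate, lower = ci$lower,
                                  upper = ci$upper)
  sens <- tp / n_pos
  spec <- tn / n_neg
  flags <- character(0)

  lr_ci <- function(lr, log_se) {
    if (!is.finite(lr) || !is.finite(log_se) || lr == 0)
      return(list(estimate = lr, lower = NA_real_, upper = NA_real_))
    list(estimate = lr, lower = lr * exp(-z * log_se),
         upper = lr * exp(z * log_se))
  }
  if (fp == 0) {
    plr <- list(estimate = Inf, lower = NA_real_, upper = NA_real_)
    flags <- c(flags, "plr_infinite")
  } else {
    plr <- lr_ci(sens / (1 - spec),
                 sqrt(max(0, 1 / tp - 1 / n_pos + 1 / fp - 1 / n_neg)))
  }
  if (spec == 0) {
    nlr <- list(estimate = Inf, lower = NA_real_, upper = NA_real_)
    flags <- c(flags, "nlr_infinite")
  } else {
    nlr <- lr_ci((1 - sens) / spec,
                 if (fn == 0) Inf else
                   sqrt(max(0, 1 / fn - 1 / n_pos + 1 / tn - 1 / n_neg)))
    if (fn == 0) nlr <- list(estimate = 0, lower = NA_real_, upper = NA_real_)
  }
  structure(
    list(sensitivity = as_triplet(wilson_ci(tp, n_pos, ci_level)),
         specificity = as_triplet(wilson_ci(tn, n_neg, ci_level)),
         accuracy = as_triplet(wilson_ci(tp + tn, n, ci_level)),
         plr = plr, nlr = nlr, n_pos = n_pos, n_neg = n_neg,
         counts = counts, flags = flags, ci_level = ci_level),
    class = "diagnostic_report")
}

#' Construct confusion counts directly from the four cells
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @return a [confusion_counts()] object.
#' @export
counts_2x2 <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_counts")
}

#' @export
print.diagnostic_report <- function(x, digits = 2, ...) {
  f <- function(m, name) {
    cat(sprintf("  %-12s %.*f (%.*f-%.*f)\n", name,
                digits, m$estimate, digits, m$lower, digits, m$upper))
  }
  cat(sprintf("<diagnostic_report> %d cancer / %d non-cancer videos\n",
              x$n_pos, x$n_neg))
  f(x$sensitivity, "sensitivity")
  f(x$specificity, "specificity")
  f(x$accuracy, "accuracy")
  for (nm in c("plr", "nlr")) {
    m <- x[[nm]]
    if (is.na(m$lower))
      cat(sprintf("  %-12s %.*f\n", toupper(nm), digits, m$estimate))
    else
      cat(sprintf("  %-12s %.*f (%.*f-%.*f)\n", toupper(nm),
                  digits, m$estimate, digits, m$lower, digits, m$upper))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Per-pathology diagnostic accuracy
#'
#' Stratifies per-video correctness (prediction equal to truth) by
#' pathology subtype and reports each stratum's proportion correct with a
#' Wilson interval. Empty strata are dropped with a warning.
#'
#' @param pathology per-video pathology subtype.
#' @param correct per-video logical, prediction matches truth.
#' @param ci_level confidence level (default 0.95).
#' @return data frame: `pathology`, `n`, `n_correct`, `accuracy`, `lower`,
#'   `upper`.
#' @export
stratified_accuracy <- function(pathology, correct, ci_level = 0.95) {
  stopifnot(length(pathology) == length(correct), is.logical(correct))
  levs <- intersect(pathology_levels(), unique(pathology))
  missing_levels <- setdiff(unique(pathology), levs)
  if (length(missing_levels))
    stop("unknown pathology: ", paste(missing_levels, collapse = ", "))
  rows <- lapply(levs, function(p) {
    idx <- pathology == p
    n <- sum(idx)
    if (n == 0L) return(NULL)
    k <- sum(correct[idx])
    ci <- wilson_ci(k, n, ci_level)
    data.frame(pathology = p, n = n, n_correct = k, accuracy = k / n,
               lower = ci$lower, upper = ci$upper, stringsAsFactors = FALSE)
  })
  dropped <- setdiff(pathology_levels(), levs)
  if (length(dropped))
    warning("empty strata omitted: ", paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e) with expected
#' agreement p_e from the product of the raters' marginals, plus the
#' large-sample confidence interval based on
#' se = sqrt(p_o (1 - p_o)) / ((1 - p_e) sqrt(n)). Symmetric in the two
#' raters and invariant to relabelling of the categories.
#'
#' @param rater_a,rater_b aligned label vectors over the same cases.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `kappa_result`: `kappa`, `lower`, `upper`, `p_o`,
#'   `p_e`, `n`.
#' @export
cohens_kappa <- function(rater_a, rater_b, conf_level = 0.95) {
  if (length(rater_a) != length(rater_b))
    stop("raters must rate the same cases")
  n <- length(rater_a)
  if (n < 2L) stop("need at least two cases")
  levs <- sort(unique(c(rater_a, rater_b)))
  tab <- table(factor(rater_a, levs), factor(rater_b, levs))
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12)
    stop("kappa undefined: both raters constant")
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / n) / (1 - p_e)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kappa, lower = kappa - z * se,
                 upper = kappa + z * se, p_o = p_o, p_e = p_e, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa %.3f (%.3f-%.3f), n = %d\n",
              x$kappa, x$lower, x$upper, x$n))
  invisible(x)
}

#' McNemar test on paired classifier correctness
#'
#' Compares two classifiers evaluated on the same cases through their
#' discordant counts: `b` cases where only the first is correct, `c` where
#' only the second is. The default is the exact two-sided binomial test of
#' b against b + c with success probability one half — appropriate because
#' discordant counts in a modest test set are small. The asymptotic
#' chi-square form (without continuity correction) is available via
#' `method = "asymptotic"`. `b = c = 0` yields p = 1 (no evidence), not an
#' error.
#'
#' @param correct_a,correct_b aligned logical vectors (each classifier's
#'   per-case correctness), or supply `b` and `c` directly.
#' @param b,c discordant counts (used when `correct_a` is missing).
#' @param method `"exact"` (default) or `"asymptotic"`.
#' @return list: `b`, `c`, `p_value`, `method`.
#' @export
mcnemar_test <- function(correct_a, correct_b, b = NULL, c = NULL,
                         method = c("exact", "asymptotic")) {
  method <- match.arg(method)
  if (!missing(correct_a)) {
    stopifnot(length(correct_a) == length(correct_b))
    b <- sum(correct_a & !correct_b)
    c <- sum(!correct_a & correct_b)
  }
  stopifnot(!is.null(b), !is.null(c), b >= 0, c >= 0)
  n <- b + c
  if (n == 0L) {
    p <- 1.0
  } else if (method == "exact") {
    p <- stats::binom.test(b, n, p = 0.5)$p.value
  } else {
    stat <- (b - c)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(b = b, c = c, p_value = min(1, p), method = method)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's X^2 without continuity correction, df = 1, upper-tail p-value.
#' Equals the hand formula N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
#'
#' @param tab 2x2 matrix of counts.
#' @return list: `statistic`, `p_value`, `df`.
#' @export
pearson_chi2_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities not
#' exceeding that of the observed table. A companion to
#' [pearson_chi2_2x2()] for small expected counts. A table with a zero
#' margin admits a single configuration and returns p = 1.
#'
#' @param tab 2x2 matrix of counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1.0)
  stats::fisher.test(tab)$p.value
}

#' Mann-Whitney U test for TTROI group comparison
#'
#' Two-sided rank-sum comparison of TTROI between the cancerous and
#' non-cancerous groups. U uses midranks for ties. The p-value is exact (by
#' enumeration) when there are no ties and n1 * n2 <= 400, otherwise the
#' normal approximation with tie-corrected variance (no continuity
#' correction) is used.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @return list: `u` (U for `group_a`), `p_value`, `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && length(group_a) * length(group_b) <= 400
  res <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = FALSE))
  p <- res$p.value
  if (is.nan(p)) p <- 1.0  # zero variance under complete ties: no evidence
  list(u = unname(res$statistic), p_value = p,
       method = if (exact) "exact" else "normal_tie_corrected")
}
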