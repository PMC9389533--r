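#' Pipeline configuration
#'
#' Bundles every tunable the end-to-end evaluation uses: the ROI gap rule
#' (3 s), the ROI end convention, the TTROI cutoff (a fixed value in
#' seconds, 1 s being the headline operating point, or `"auto"` for
#' in-sample Youden selection), the confidence level, and — when inputs are
#' synthetic — the generator parameters, cohort composition and master
#' seed.
#'
#' @param gap_s ROI gap rule in seconds (default 3).
#' @param roi_end ROI end convention, see [extract_rois()].
#' @param cutoff_s numeric cutoff in seconds, or `"auto"`.
#' @param ci_level confidence level for all intervals.
#' @param seed master seed for simulation.
#' @param sim_params a [sim_params()] object.
#' @param cohort a [cohort_spec()] object.
#' @param out_dir optional directory; when given, every stage's table is
#'   written there as TSV/CSV/JSON.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(gap_s = 3.0,
                            roi_end = c("last_tag", "last_tag_plus_gap"),
                            cutoff_s = 1.0, ci_level = 0.95, seed = 1L,
                            sim_params = default_params(),
                            cohort = default_cohort(), out_dir = NULL) {
  roi_end <- match.arg(roi_end)
  stopifnot(gap_s > 0,
            identical(cutoff_s, "auto") || (is.numeric(cutoff_s) && cutoff_s >= 0))
  structure(list(gap_s = gap_s, roi_end = roi_end, cutoff_s = cutoff_s,
                 ci_level = ci_level, seed = as.integer(seed),
                 sim_params = sim_params, cohort = cohort, out_dir = out_dir),
            class = "pipeline_config")
}

#' Evaluate classified videos against ground truth
#'
#' Joins the per-video summary table with metadata, applies the cutoff, and
#' computes the full report: confusion counts, diagnostic metrics with
#' intervals, per-pathology stratified accuracy, the Mann-Whitney
#' comparison of TTROI between the truth groups, and the chi-square
#' comparison of the no-ROI proportions.
#'
#' @param summaries data frame from [summarize_videos()].
#' @param meta metadata data frame (see [read_video_meta()]).
#' @param cutoff_s TTROI cutoff in seconds.
#' @param ci_level confidence level.
#' @return list of class `evaluation`: `per_video`, `counts`, `metrics`,
#'   `by_pathology`, `ttroi_test`, `no_roi_test`, `cutoff_s`.
#' @export
evaluate_cohort <- function(summaries, meta, cutoff_s = 1.0, ci_level = 0.95) {
  meta <- validate_video_meta(meta)
  if (!setequal(summaries$video_id, meta$video_id))
    stop("summaries and metadata cover different video_ids")
  df <- merge(summaries, meta, by = "video_id", sort = TRUE)
  df$prediction <- classify_video(df$ttroi_s, cutoff_s)
  df$correct <- df$prediction == df$truth
  counts <- confusion_counts(df$truth, df$prediction)
  metrics <- diagnostic_metrics(counts, ci_level)
  by_path <- stratified_accuracy(df$pathology, df$correct, ci_level)
  pos <- df$truth == "cancer"
  ttroi_test <- if (any(pos) && any(!pos))
    mann_whitney(df$ttroi_s[pos], df$ttroi_s[!pos]) else NULL
  no_roi_tab <- table(factor(df$truth, c("cancer", "non_cancer")),
                      factor(!df$has_roi, c(FALSE, TRUE)))
  no_roi_test <- if (all(rowSums(no_roi_tab) > 0) && all(colSums(no_roi_tab) > 0))
    pearson_chi2_2x2(no_roi_tab) else NULL
  structure(list(per_video = df, counts = counts, metrics = metrics,
                 by_pathology = by_path, ttroi_test = ttroi_test,
                 no_roi_test = no_roi_test, cutoff_s = cutoff_s),
            class = "evaluation")
}

#' @export
print.evaluation <- function(x, ...) {
  cat(sprintf("<evaluation> cutoff %.3g s\n", x$cutoff_s))
  print(x$counts)
  print(x$metrics)
  cat("  per-pathology accuracy:\n")
  print(x$by_pathology, row.names = FALSE)
  if (!is.null(x$ttroi_test))
    cat(sprintf("  TTROI Mann-Whitney p = %.4g\n", x$ttroi_test$p_value))
  if (!is.null(x$no_roi_test))
    cat(sprintf("  no-ROI chi-square p = %.4g\n", x$no_roi_test$p_value))
  invisible(x)
}

#' Run the full evaluation pipeline
#'
#' Simulate (or accept) a cohort, extract ROIs and TTROI per video, pick or
#' apply the cutoff, classify, and evaluate. Re-running with the same
#' config reproduces every output. When `config$out_dir` is set, writes
#' `metadata.csv`, `video_summaries.tsv`, `roc_points.tsv` (if cutoff is
#' `"auto"`), `per_video.tsv`, `report.json` and a config echo
#' `run_config.json`.
#'
#' @param config a [pipeline_config()].
#' @param cohort_data optional pre-built list with `meta` and `series` (as
#'   returned by [simulate_cohort()]); when `NULL` the cohort is simulated
#'   from the config.
#' @return list of class `pipeline_result`: `meta`, `summaries`, `roc` (or
#'   `NULL`), `cutoff_s`, `evaluation`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort_data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort_data))
    cohort_data <- simulate_cohort(config$cohort, config$sim_params,
                                   seed = config$seed)
  meta <- validate_video_meta(cohort_data$meta)
  summaries <- summarize_videos(cohort_data$series, gap_s = config$gap_s,
                                roi_end = config$roi_end)
  roc <- NULL
  cutoff_s <- config$cutoff_s
  if (identical(cutoff_s, "auto")) {
    joined <- merge(summaries, meta[, c("video_id", "truth")], by = "video_id")
    roc <- roc_points(joined$ttroi_s, joined$truth)
    cutoff_s <- best_cutoff(roc)
  }
  ev <- evaluate_cohort(summaries, meta, cutoff_s = cutoff_s,
                        ci_level = config$ci_level)
  res <- structure(list(meta = meta, summaries = summaries, roc = roc,
                        cutoff_s = cutoff_s, evaluation = ev,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

#' @noRd
triplet_row <- function(m) c(estimate = m$estimate, lower = m$lower,
                             upper = m$upper)

#' Flatten an evaluation into a one-row metric table
#'
#' @param ev an [evaluate_cohort()] result.
#' @return data frame with one row per metric (`metric`, `estimate`,
#'   `lower`, `upper`).
#' @export
metrics_table <- function(ev) {
  stopifnot(inherits(ev, "evaluation"))
  m <- ev$metrics
  out <- rbind(sensitivity = triplet_row(m$sensitivity),
               specificity = triplet_row(m$specificity),
               accuracy = triplet_row(m$accuracy),
               plr = triplet_row(m$plr), nlr = triplet_row(m$nlr))
  data.frame(metric = rownames(out), out, row.names = NULL)
}

#' @noRd
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$meta, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.table(res$summaries, file.path(out_dir, "video_summaries.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$roc))
    utils::write.table(res$roc$points, file.path(out_dir, "roc_points.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$evaluation$per_video,
                     file.path(out_dir, "per_video.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  report <- list(
    cutoff_s = res$cutoff_s,
    auc = if (!is.null(res$roc)) res$roc$auc else NULL,
    counts = unclass(res$evaluation$counts),
    metrics = metrics_table(res$evaluation),
    by_pathology = res$evaluation$by_pathology,
    ttroi_mann_whitney_p = if (!is.null(res$evaluation$ttroi_test))
      res$evaluation$ttroi_test$p_value else NULL,
    no_roi_chi2_p = if (!is.null(res$evaluation$no_roi_test))
      res$evaluation$no_roi_test$p_value else NULL)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- res$config
  cfg$out_dir <- NULL  # location, not science: keep the echo reproducible
  cfg$sim_params$emission <- apply(cfg$sim_params$emission, 1, identity,
                                   simplify = FALSE)
  jsonlite::write_json(list(config = unclass(cfg),
                            r_version = as.character(getRversion())),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
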