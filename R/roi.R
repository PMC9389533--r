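#' Merge cancer tags into regions of interest (gap rule)
#'
#' A region of interest (ROI) starts at any cancer recognition tag and ends
#' when no new cancer tag appears within `gap_s` seconds: cancer-tagged
#' timestamps are partitioned into maximal runs in which consecutive tags
#' are at most `gap_s` apart (closed comparison, so a gap of exactly
#' `gap_s` still joins). A single isolated tag forms an ROI of zero
#' duration. Records are collapsed per frame time first, so duplicate
#' timestamps cannot double-count.
#'
#' @param series a [frame_series()].
#' @param gap_s maximal within-ROI gap between consecutive cancer tags, in
#'   seconds (default 3).
#' @param roi_end convention for the ROI end time: `"last_tag"` (default;
#'   the timestamp of the last cancer tag in the run) or
#'   `"last_tag_plus_gap"` (the last tag plus `gap_s`, clipped to the video
#'   duration). Only the default is used for the headline statistics.
#' @return data frame with one row per ROI: `start_s`, `end_s`, `n_tags`,
#'   time-ordered and disjoint (consecutive ROIs are separated by more than
#'   `gap_s`). Zero rows when the stream has no cancer tags.
#' @examples
#' s <- frame_series("v", data.frame(t = c(10, 11, 12.5, 20),
#'                                   label = "cancer"), duration_s = 30)
#' extract_rois(s)  # two ROIs: [10, 12.5] and [20, 20]
#' @export
extract_rois <- function(series, gap_s = 3.0,
                         roi_end = c("last_tag", "last_tag_plus_gap")) {
  stopifnot(inherits(series, "frame_series"), is.numeric(gap_s), gap_s > 0)
  roi_end <- match.arg(roi_end)
  if (nrow(series$records) == 0L) stop("empty stream")
  r <- series$records
  if (anyDuplicated(r$t)) r <- collapse_frames(series)$records
  tt <- r$t[r$label == "cancer"]
  if (length(tt) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_tags = integer(0)))
  tt <- sort(tt)
  new_run <- c(TRUE, diff(tt) > gap_s)
  run <- cumsum(new_run)
  start_s <- tapply(tt, run, min)
  end_s <- tapply(tt, run, max)
  n_tags <- tapply(tt, run, length)
  out <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                    n_tags = as.integer(n_tags))
  if (roi_end == "last_tag_plus_gap")
    out$end_s <- pmin(out$end_s + gap_s, series$duration_s)
  rownames(out) <- NULL
  out
}

#' Summarise a video by its TTROI
#'
#' Computes the total time of the regions of interest (TTROI): the sum of
#' ROI durations extracted by [extract_rois()]. TTROI is the video-level
#' decision statistic — a longer total cancer-tag dwell time indicates the
#' lesion is more likely to be early gastric cancer. `has_roi` is `TRUE`
#' iff the stream carries at least one cancer tag.
#'
#' @inheritParams extract_rois
#' @return list of class `video_summary`: `video_id`, `rois` (as
#'   [extract_rois()]), `ttroi_s`, `has_roi`, `n_rois`, `duration_s`.
#' @export
summarize_video <- function(series, gap_s = 3.0,
                            roi_end = c("last_tag", "last_tag_plus_gap")) {
  rois <- extract_rois(series, gap_s = gap_s, roi_end = roi_end)
  structure(
    list(video_id = series$video_id, rois = rois,
         ttroi_s = sum(rois$end_s - rois$start_s),
         has_roi = nrow(rois) > 0L, n_rois = nrow(rois),
         duration_s = series$duration_s),
    class = "video_summary")
}

#' @export
print.video_summary <- function(x, ...) {
  cat(sprintf("<video_summary> %s: %d ROI(s), TTROI %.3f s over %.1f s\n",
              x$video_id, x$n_rois, x$ttroi_s, x$duration_s))
  invisible(x)
}

#' Summarise many videos into a table
#'
#' Applies [summarize_video()] to a list of series and stacks the results
#' into the per-video summary table the downstream ROC and evaluation
#' stages consume.
#'
#' @param series_list list of [frame_series()] objects.
#' @inheritParams extract_rois
#' @return data frame with columns `video_id`, `n_rois`, `ttroi_s`,
#'   `has_roi`.
#' @export
summarize_videos <- function(series_list, gap_s = 3.0,
                             roi_end = c("last_tag", "last_tag_plus_gap")) {
  roi_end <- match.arg(roi_end)
  rows <- lapply(series_list, function(s) {
    v <- summarize_video(s, gap_s = gap_s, roi_end = roi_end)
    data.frame(video_id = v$video_id, n_rois = v$n_rois,
               ttroi_s = v$ttroi_s, has_roi = v$has_roi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
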