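#' Frame label vocabulary
#'
#' The closed set of per-frame labels a detection stream may carry:
#' `"cancer"` (a cancer recognition tag), `"benign"` (benign lesion tag),
#' `"background"` (background mucosa tag) and `"none"` (no rectangle drawn
#' for that frame). `"none"` is distinct from `"background"`: the detector
#' draws class-coloured frames only on recognised content, so absent output
#' must be representable.
#'
#' @export
frame_labels <- function() c("cancer", "benign", "background", "none")

#' @noRd
vienna_levels <- function() c("C1", "C2", "C3", "C4", "C5")

#' Pathology subtype vocabulary
#'
#' The seven pathology subtypes carried in video metadata. The two EGC
#' (early gastric cancer) subtypes imply `truth = "cancer"`; the rest are
#' non-cancerous. LGIN (low-grade intraepithelial neoplasia, Vienna C3) is
#' deliberately grouped with the non-cancerous lesions.
#'
#' @export
pathology_levels <- function() {
  c("inflammation", "atrophy", "IM", "atrophy_IM", "LGIN",
    "EGC_poor_diff", "EGC_diff")
}

empty_records <- function() {
  data.frame(t = numeric(0), label = character(0), confidence = numeric(0),
             x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0),
             stringsAsFactors = FALSE)
}

normalize_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (!all(c("t", "label") %in% names(records)))
    stop("records must have columns 't' and 'label'")
  for (col in c("confidence", "x", "y", "w", "h"))
    if (is.null(records[[col]])) records[[col]] <- NA_real_
  records <- records[c("t", "label", "confidence", "x", "y", "w", "h")]
  records$t <- as.numeric(records$t)
  records$label <- as.character(records$label)
  for (col in c("confidence", "x", "y", "w", "h"))
    records[[col]] <- as.numeric(records[[col]])
  rownames(records) <- NULL
  records
}

#' Construct a per-frame detection stream for one video
#'
#' A `frame_series` holds the classifier output for a single video: one
#' record per emitted detection with a timestamp `t` in seconds from video
#' start, a label from [frame_labels()], and optional confidence and
#' normalised bounding box `(x, y, w, h)`. Records are kept sorted by time;
#' unsorted input is sorted with a warning. Several records may share a
#' timestamp (a detector can emit more than one box per frame); see
#' [collapse_frames()].
#'
#' @param video_id single character identifier.
#' @param records data frame with columns `t`, `label` and optionally
#'   `confidence`, `x`, `y`, `w`, `h` (`NA` where absent).
#' @param duration_s video length in seconds; defaults to the last timestamp.
#' @param fps nominal frame rate (default 30).
#' @return an object of class `frame_series`.
#' @export
frame_series <- function(video_id, records, duration_s = NULL, fps = 30) {
  stopifnot(is.character(video_id), length(video_id) == 1L)
  records <- normalize_records(records)
  if (nrow(records) == 0L) stop("empty stream: a frame_series needs at least one record")
  if (is.unsorted(records$t)) {
    warning("records not sorted by t; sorting")
    records <- records[order(records$t), , drop = FALSE]
    rownames(records) <- NULL
  }
  if (is.null(duration_s)) duration_s <- max(records$t)
  x <- structure(
    list(video_id = video_id, records = records,
         duration_s = as.numeric(duration_s), fps = as.numeric(fps)),
    class = "frame_series")
  validate_frame_series(x)
}

#' @noRd
validate_frame_series <- function(x) {
  r <- x$records
  if (any(r$t < 0)) stop("timestamps must be non-negative")
  if (any(r$t > x$duration_s + 1e-9)) stop("timestamps exceed duration_s")
  bad <- setdiff(unique(r$label), frame_labels())
  if (length(bad))
    stop("unknown labels: ", paste(bad, collapse = ", "))
  has_box <- !is.na(r$x) | !is.na(r$y) | !is.na(r$w) | !is.na(r$h)
  if (any(has_box)) {
    b <- r[has_box, c("x", "y", "w", "h")]
    if (anyNA(b)) stop("incomplete bounding box (need all of x, y, w, h)")
    ok <- b$x >= 0 & b$y >= 0 & b$w > 0 & b$h > 0 &
      b$x + b$w <= 1 + 1e-9 & b$y + b$h <= 1 + 1e-9
    if (!all(ok)) stop("bounding boxes must be normalised to [0,1]")
  }
  if (!is.finite(x$fps) || x$fps <= 0) stop("fps must be positive")
  x
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %s: %d records over %.1f s (%g fps)\n",
              x$video_id, nrow(x$records), x$duration_s, x$fps))
  tab <- table(factor(x$records$label, levels = frame_labels()))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Read a per-frame detection stream
#'
#' Reads one video's detection stream from disk. Two dialects are supported:
#' `"jsonl"` (one JSON object per line with keys `video_id`, `t`, `label`
#' and optional `confidence`, `box = [x, y, w, h]`) and `"csv"` (header
#' `video_id,t,label,confidence,x,y,w,h`, empty cells for absent optionals).
#' The two dialects are interchangeable: the same logical stream parses to
#' an equal `frame_series` from either.
#'
#' @param path file to read.
#' @param dialect `"jsonl"` or `"csv"`.
#' @return a [frame_series()].
#' @export
read_detection_stream <- function(path, dialect = c("jsonl", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty stream: ", path)
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) stop("parse error at line ", i, ": ",
                                               conditionMessage(e), call. = FALSE))
      for (f in c("video_id", "t", "label"))
        if (is.null(obj[[f]]))
          stop("parse error at line ", i, ": missing required field '", f, "'",
               call. = FALSE)
      box <- obj$box
      if (!is.null(box) && length(box) != 4L)
        stop("parse error at line ", i, ": box must have 4 elements", call. = FALSE)
      recs[[i]] <- data.frame(
        video_id = obj$video_id, t = obj$t, label = obj$label,
        confidence = if (is.null(obj$confidence)) NA_real_ else obj$confidence,
        x = if (is.null(box)) NA_real_ else box[[1]],
        y = if (is.null(box)) NA_real_ else box[[2]],
        w = if (is.null(box)) NA_real_ else box[[3]],
        h = if (is.null(box)) NA_real_ else box[[4]],
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, recs)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("video_id", "t", "label")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("parse error: missing required column(s) ", paste(miss, collapse = ", "))
    if (nrow(df) == 0L) stop("empty stream: ", path)
    if (anyNA(df$label) || any(!nzchar(df$label))) {
      bad <- which(is.na(df$label) | !nzchar(df$label))[1]
      stop("parse error at line ", bad + 1L, ": missing required field 'label'")
    }
    if (anyNA(df$t)) {
      bad <- which(is.na(df$t))[1]
      stop("parse error at line ", bad + 1L, ": missing required field 't'")
    }
  }
  vid <- unique(df$video_id)
  if (length(vid) != 1L) stop("stream mixes video_ids: ", paste(vid, collapse = ", "))
  frame_series(vid, df[setdiff(names(df), "video_id")])
}

#' Write a per-frame detection stream
#'
#' Inverse of [read_detection_stream()]: round-tripping reproduces the
#' series up to floating-point formatting (at least 6 significant digits are
#' written). Refuses to write an empty stream.
#'
#' @param series a [frame_series()].
#' @param path destination file.
#' @param dialect `"jsonl"` or `"csv"`.
#' @export
write_detection_stream <- function(series, path, dialect = c("jsonl", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(series, "frame_series"))
  r <- series$records
  if (nrow(r) == 0L) stop("refusing to write an empty stream")
  if (dialect == "jsonl") {
    lines <- vapply(seq_len(nrow(r)), function(i) {
      obj <- list(video_id = series$video_id, t = r$t[i], label = r$label[i])
      if (!is.na(r$confidence[i])) obj$confidence <- r$confidence[i]
      if (!is.na(r$x[i])) obj$box <- c(r$x[i], r$y[i], r$w[i], r$h[i])
      jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(10))
    }, character(1))
    writeLines(lines, path)
  } else {
    out <- cbind(video_id = series$video_id, r)
    utils::write.csv(format(out, digits = 10, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

#' Collapse co-timestamped records to one label
#'
#' An object detector may emit several boxes (hence several records) for a
#' single frame, while the diagnostic rules treat each frame as carrying one
#' label. `collapse_labels()` reduces a set of labels to the highest-priority
#' one (cancer > benign > background > none); `collapse_frames()` applies it
#' per distinct timestamp of a series, returning a series with exactly one
#' record per frame time (confidence and box columns are dropped to `NA`
#' where records merged).
#'
#' @param labels character vector of labels sharing a timestamp.
#' @return `collapse_labels`: a single label. `collapse_frames`: a
#'   [frame_series()].
#' @export
collapse_labels <- function(labels) {
  stopifnot(length(labels) >= 1L, all(labels %in% frame_labels()))
  frame_labels()[min(match(labels, frame_labels()))]
}

#' @rdname collapse_labels
#' @param series a [frame_series()].
#' @export
collapse_frames <- function(series) {
  stopifnot(inherits(series, "frame_series"))
  r <- series$records
  if (!anyDuplicated(r$t)) return(series)
  spl <- split(seq_len(nrow(r)), r$t)
  out <- lapply(spl, function(idx) {
    if (length(idx) == 1L) return(r[idx, , drop = FALSE])
    data.frame(t = r$t[idx[1]], label = collapse_labels(r$label[idx]),
               confidence = NA_real_, x = NA_real_, y = NA_real_,
               w = NA_real_, h = NA_real_, stringsAsFactors = FALSE)
  })
  frame_series(series$video_id, do.call(rbind, out),
               duration_s = series$duration_s, fps = series$fps)
}

#' Map revised Vienna category to binary ground truth
#'
#' Revised Vienna classification categories C4 (mucosal high-grade
#' neoplasia) and C5 (submucosal invasion by neoplasia) define cancer; C1
#' (negative), C2 (indefinite) and C3 (mucosal low-grade neoplasia, LGIN)
#' are non-cancerous. Vectorised.
#'
#' @param category character vector of categories in `C1`..`C5`.
#' @return character vector of `"cancer"` / `"non_cancer"`.
#' @examples
#' map_vienna_to_truth(c("C1", "C3", "C4", "C5"))
#' @export
map_vienna_to_truth <- function(category) {
  bad <- setdiff(unique(category), vienna_levels())
  if (length(bad)) stop("unknown Vienna category: ", paste(bad, collapse = ", "))
  ifelse(category %in% c("C4", "C5"), "cancer", "non_cancer")
}

#' Read a per-video metadata table
#'
#' CSV with header `video_id,pathology,vienna,truth,severity,range,location,sex`.
#' `truth` may be omitted, in which case it is derived from `vienna` via
#' [map_vienna_to_truth()]. Consistency between `truth`, `vienna` and the
#' EGC pathology subtypes is enforced.
#'
#' @param path CSV file.
#' @return data frame of video metadata.
#' @export
read_video_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_video_meta(df)
}

#' @noRd
validate_video_meta <- function(df) {
  need <- c("video_id", "pathology", "vienna")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$pathology), pathology_levels())
  if (length(bad)) stop("unknown pathology: ", paste(bad, collapse = ", "))
  derived <- map_vienna_to_truth(df$vienna)
  if (is.null(df$truth) || all(is.na(df$truth))) {
    df$truth <- derived
  } else if (any(df$truth != derived)) {
    stop("truth column inconsistent with Vienna categories")
  }
  is_egc <- df$pathology %in% c("EGC_poor_diff", "EGC_diff")
  if (any(is_egc != (df$truth == "cancer")))
    stop("EGC pathology subtypes must have truth = cancer and vice versa")
  for (col in c("severity", "range", "location", "sex"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  df
}
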