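#' Read a pose-tracking CSV (DeepLabCut dialect)
#'
#' Reads one body part's track from a DeepLabCut-style CSV table. The dialect
#' has three header rows (`scorer`, `bodyparts`, `coords`) followed by data
#' rows whose first column is the frame index; each body part contributes an
#' `x`, `y` and `likelihood` column.
#'
#' @param path Path to the CSV file.
#' @param bodypart Name of the body part to extract. Defaults to
#'   `"bodycenter"`, the body-centre keypoint used for movement metrics.
#' @param fps Source frame rate in frames per second (video default 30).
#' @return A `raw_track`: a data frame with columns `frame`, `time` (s), `x`,
#'   `y`, `likelihood` and attributes `fps` and `bodypart`. Frame indices are
#'   0-based; `time = frame / fps`.
#' @seealso [write_pose_csv()], [filter_confidence()], [thin_track()]
#' @export
read_pose_csv <- function(path, bodypart = "bodycenter", fps = 30) {
  raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  if (nrow(raw) < 4L || tolower(raw[1, 1]) != "scorer" ||
      tolower(raw[2, 1]) != "bodyparts" || tolower(raw[3, 1]) != "coords")
    stop("malformed pose CSV: expected 3 header rows scorer/bodyparts/coords")
  parts <- as.character(raw[2, -1])
  coords <- tolower(as.character(raw[3, -1]))
  if (!all(c("x", "y", "likelihood") %in% coords))
    stop("malformed pose CSV: third header row must contain x, y and likelihood")
  idx <- which(parts == bodypart)
  if (length(idx) == 0L)
    stop(sprintf("bodypart '%s' not found; available: %s",
                 bodypart, paste(unique(parts), collapse = ", ")))
  col_of <- function(what) {
    j <- idx[coords[idx] == what]
    if (length(j) != 1L)
      stop(sprintf("malformed pose CSV: bodypart '%s' lacks a unique '%s' column",
                   bodypart, what))
    j + 1L  # offset for the leading frame-index column
  }
  dat <- raw[-(1:3), , drop = FALSE]
  frame <- as.integer(dat[[1]])
  track <- data.frame(
    frame = frame,
    time = frame / fps,
    x = as.numeric(dat[[col_of("x")]]),
    y = as.numeric(dat[[col_of("y")]]),
    likelihood = as.numeric(dat[[col_of("likelihood")]])
  )
  new_raw_track(track, fps = fps, bodypart = bodypart)
}

new_raw_track <- function(df, fps, bodypart = "bodycenter") {
  stopifnot(all(c("frame", "time", "x", "y", "likelihood") %in% names(df)))
  if (is.unsorted(df$frame, strictly = TRUE))
    stop("frame indices must be strictly increasing")
  if (any(df$likelihood < 0 | df$likelihood > 1, na.rm = TRUE))
    stop("likelihood values must lie in [0, 1]")
  structure(df, fps = fps, bodypart = bodypart,
            class = c("raw_track", "data.frame"))
}

#' Write a track as a pose-tracking CSV (DeepLabCut dialect)
#'
#' Inverse of [read_pose_csv()] for a single body part; coordinates are
#' written with enough precision to round-trip to at least 6 decimals.
#'
#' @param track A `raw_track` (or data frame with `frame`, `x`, `y`,
#'   `likelihood`).
#' @param path Output file path.
#' @param scorer Scorer label for the first header row.
#' @param bodypart Body-part label; defaults to the track's attribute.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(track, path, scorer = "cliffhmm",
                           bodypart = attr(track, "bodypart") %||% "bodycenter") {
  hdr <- rbind(
    c("scorer", rep(scorer, 3L)),
    c("bodyparts", rep(bodypart, 3L)),
    c("coords", "x", "y", "likelihood")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(hdr, 1L, paste, collapse = ","), con)
  body <- sprintf("%d,%.10g,%.10g,%.10g",
                  track$frame, track$x, track$y, track$likelihood)
  writeLines(body, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop low-confidence frames
#'
#' Retains only frames whose tracking likelihood meets the confidence
#' threshold (default 90%). Original frame indices are preserved, so the
#' result may contain gaps; see [segment_gaps()].
#'
#' @param track A `raw_track`.
#' @param threshold Minimum likelihood in `[0, 1]`; default `0.9`.
#' @return The filtered `raw_track`.
#' @export
filter_confidence <- function(track, threshold = 0.9) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- track$likelihood >= threshold
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no frames pass the confidence threshold; returning an empty track")
  new_raw_track(out, fps = attr(track, "fps"), bodypart = attr(track, "bodypart"))
}

#' Thin a track to a lower effective frame rate
#'
#' Keeps every `k`-th retained frame, reducing the effective frame rate to
#' `fps / k` (e.g. `k = 3` turns a 30 fps source into 10 fps, `k = 5` into
#' 6 fps). Thinning coarsens steps but preserves the distributional shape of
#' movement metrics.
#'
#' @param track A `raw_track`.
#' @param k Positive integer thinning factor.
#' @return The thinned `raw_track` with updated `fps` attribute.
#' @export
thin_track <- function(track, k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != as.integer(k))
    stop("k must be a positive integer")
  k <- as.integer(k)
  out <- track[seq(1L, nrow(track), by = k), , drop = FALSE]
  rownames(out) <- NULL
  new_raw_track(out, fps = attr(track, "fps") / k,
                bodypart = attr(track, "bodypart"))
}

#' Split a track into contiguous segments at large gaps
#'
#' Confidence filtering leaves holes in the frame sequence; steps computed
#' across a long hole are not single-interval movements, so tracks are cut
#' wherever consecutive retained frames are more than `max_gap` source frames
#' apart. Segments shorter than 2 frames are dropped.
#'
#' @param track A `raw_track`.
#' @param max_gap Maximum allowed frame-index difference (default 5).
#' @return A list of `raw_track` segments.
#' @export
segment_gaps <- function(track, max_gap = 5) {
  stopifnot(max_gap >= 1)
  n <- nrow(track)
  if (n == 0L) return(list())
  brk <- which(diff(track$frame) > max_gap)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  segs <- Map(function(s, e) {
    seg <- track[s:e, , drop = FALSE]
    rownames(seg) <- NULL
    new_raw_track(seg, fps = attr(track, "fps"), bodypart = attr(track, "bodypart"))
  }, starts, ends)
  segs[vapply(segs, nrow, 1L) >= 2L]
}
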