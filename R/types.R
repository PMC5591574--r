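# Core data containers. All are plain lists with S3 classes and validating
# constructors, in the style of base R modelling objects.

#' Construct a multi-channel EOG recording
#'
#' Container for raw periocular EOG samples. The four electrode roles follow
#' the standard montage for eye-writing: electrodes at the left and right
#' outer canthi and above and below one eye.
#'
#' @param samples Numeric matrix, one row per sample and one column per
#'   channel, in microvolts.
#' @param rate Sampling rate in Hz (> 0).
#' @param channels Named integer vector mapping the roles `left`, `right`,
#'   `above`, `below` to column indices of `samples`.
#' @param meta Optional named list of free-form metadata (participant id,
#'   trial, intended digit, ...).
#' @return An object of class `eog_recording`.
#' @examples
#' x <- matrix(rnorm(400), ncol = 4)
#' rec <- eog_recording(x, rate = 64)
#' rec
#' @export
eog_recording <- function(samples, rate,
                          channels = c(left = 1L, right = 2L, above = 3L, below = 4L),
                          meta = list()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop_arg("'rate' must be a single positive number")
  }
  if (nrow(samples) < 2L) stop_arg("a recording needs at least 2 samples")
  roles <- c("left", "right", "above", "below")
  if (!all(roles %in% names(channels))) {
    stop_arg(
      "channel layout must map all of: ", paste(roles, collapse = ", "),
      " (missing: ", paste(setdiff(roles, names(channels)), collapse = ", "), ")"
    )
  }
  idx <- as.integer(channels[roles])
  if (anyNA(idx) || any(idx < 1L) || any(idx > ncol(samples))) {
    stop_arg("channel layout refers to columns outside the sample matrix")
  }
  if (anyDuplicated(idx)) stop_arg("channel roles must map to distinct columns")
  structure(
    list(
      samples = samples, rate = as.numeric(rate),
      channels = stats::setNames(idx, roles), meta = meta
    ),
    class = "eog_recording"
  )
}

#' @export
print.eog_recording <- function(x, ...) {
  cat(
    sprintf(
      "<eog_recording> %d samples x %d channels @ %g Hz (%.2f s)\n",
      nrow(x$samples), ncol(x$samples), x$rate, nrow(x$samples) / x$rate
    )
  )
  cat("  roles:", paste(names(x$channels), x$channels, sep = "=", collapse = " "), "\n")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# Extract a role channel as a numeric vector.
channel <- function(rec, role) {
  rec$samples[, rec$channels[[role]]]
}

#' Construct a bipolar EOG signal pair
#'
#' Holds the horizontal (right minus left) and vertical (above minus below)
#' derived EOG components.
#'
#' @param h Horizontal component, microvolts.
#' @param v Vertical component, microvolts; same length as `h`.
#' @param rate Sampling rate in Hz.
#' @return An object of class `bipolar_signal`.
#' @export
bipolar_signal <- function(h, v, rate) {
  h <- as.numeric(h)
  v <- as.numeric(v)
  if (length(h) != length(v)) stop_arg("'h' and 'v' must have the same length")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop_arg("'rate' must be a single positive number")
  }
  structure(list(h = h, v = v, rate = as.numeric(rate)), class = "bipolar_signal")
}

#' @export
print.bipolar_signal <- function(x, ...) {
  cat(sprintf(
    "<bipolar_signal> %d samples @ %g Hz; h range [%.1f, %.1f] uV, v range [%.1f, %.1f] uV\n",
    length(x$h), x$rate, min(x$h), max(x$h), min(x$v), max(x$v)
  ))
  invisible(x)
}

#' Construct a 2-D eye-writing trace
#'
#' An ordered sequence of gaze points, typically restricted to saccadic
#' samples, resampled to equal arc-length spacing and normalized to the unit
#' box before classification.
#'
#' @param points Two-column numeric matrix of (x, y) gaze coordinates.
#' @param normalized Logical; `TRUE` once the trace spans `[0,1] x [0,1]`.
#' @param meta Optional named list of provenance (source file, estimated
#'   crosstalk coefficient, ...).
#' @return An object of class `eye_trace`.
#' @export
eye_trace <- function(points, normalized = FALSE, meta = list()) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop_arg("'points' must have exactly 2 columns (x, y)")
  if (nrow(points) < 2L) stop_arg("a trace needs at least 2 points")
  colnames(points) <- c("x", "y")
  structure(
    list(points = points, normalized = isTRUE(normalized), meta = meta),
    class = "eye_trace"
  )
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf(
    "<eye_trace> %d points%s; x [%.3g, %.3g], y [%.3g, %.3g]\n",
    nrow(x$points), if (x$normalized) " (normalized)" else "",
    min(x$points[, 1]), max(x$points[, 1]),
    min(x$points[, 2]), max(x$points[, 2])
  ))
  invisible(x)
}

#' Construct a saccade mask
#'
#' @param mask Logical vector, `TRUE` for saccadic samples.
#' @param threshold The wavelet-coefficient threshold used (> 0).
#' @param segments Optional 2-column matrix of (start, end) runs; derived from
#'   `mask` when omitted.
#' @return An object of class `saccade_mask`.
#' @export
saccade_mask <- function(mask, threshold, segments = NULL) {
  mask <- as.logical(mask)
  if (!is.numeric(threshold) || threshold <= 0) stop_arg("'threshold' must be > 0")
  if (is.null(segments)) segments <- true_runs(mask)
  structure(
    list(mask = mask, segments = segments, threshold = as.numeric(threshold)),
    class = "saccade_mask"
  )
}

#' @export
print.saccade_mask <- function(x, ...) {
  cat(sprintf(
    "<saccade_mask> %d/%d saccadic samples in %d segments (threshold %g)\n",
    sum(x$mask), length(x$mask), nrow(x$segments), x$threshold
  ))
  invisible(x)
}

#' Construct a digit template
#'
#' A canonical eye-writing pattern for one Arabic digit, given as an ordered
#' polyline of vertices on a 3 x 3 writing lattice (columns and rows 0..2,
#' origin bottom-left, y up). Writing starts at the first waypoint.
#'
#' @param label Integer digit 0-9.
#' @param waypoints Two-column numeric matrix of (column, row) lattice
#'   vertices; consecutive waypoints must differ.
#' @return An object of class `digit_template`.
#' @export
digit_template <- function(label, waypoints) {
  label <- as.integer(label)
  if (is.na(label) || label < 0L || label > 9L) stop_arg("'label' must be a digit 0-9")
  waypoints <- as.matrix(waypoints)
  storage.mode(waypoints) <- "double"
  if (ncol(waypoints) != 2L || nrow(waypoints) < 2L) {
    stop_arg("'waypoints' must be a matrix of >= 2 (column, row) pairs")
  }
  same <- rowSums(abs(diff(waypoints))) == 0
  if (any(same)) stop_arg("consecutive waypoints must be distinct")
  colnames(waypoints) <- c("col", "row")
  structure(list(label = label, waypoints = waypoints), class = "digit_template")
}

#' @export
print.digit_template <- function(x, ...) {
  cat(sprintf(
    "<digit_template> '%d' with %d waypoints: %s\n", x$label, nrow(x$waypoints),
    paste(sprintf("(%g,%g)", x$waypoints[, 1], x$waypoints[, 2]), collapse = " ")
  ))
  invisible(x)
}
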