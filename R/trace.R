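# Trace reconstruction: from a bipolar signal and saccade mask to a
# normalized 2-D eye-writing trace, including the calibration-free removal
# of horizontal-to-vertical crosstalk.

#' Extract the saccadic trace from a bipolar signal
#'
#' Keeps the (h, v) samples inside the saccadic segments, concatenated in
#' time order. Fixation samples are dropped, matching the convention that
#' digit templates contain no fixation parts.
#'
#' @param sig A [bipolar_signal()].
#' @param mask A [saccade_mask()] aligned to `sig`.
#' @return An [eye_trace()] (not yet normalized).
#' @export
extract_trace <- function(sig, mask) {
  stopifnot(inherits(sig, "bipolar_signal"), inherits(mask, "saccade_mask"))
  if (length(mask$mask) != length(sig$h)) {
    stop_arg("mask length does not match the signal")
  }
  keep <- which(mask$mask)
  if (length(keep) < 2L) {
    stop_arg("degenerate trace: no saccadic samples above the threshold")
  }
  eye_trace(cbind(sig$h[keep], sig$v[keep]),
    meta = list(n_segments = nrow(mask$segments), threshold = mask$threshold)
  )
}

#' Resample a trace to equidistant points
#'
#' Places `n_points` points at equal arc-length spacing along the polyline
#' of the input; endpoints are preserved. Consecutive points are then
#' separated by equal Euclidean gaps wherever the path is locally straight
#' (the gap shortens marginally where a corner falls between two samples).
#' This makes traces comparable point-by-point regardless of writing speed.
#'
#' @param trace An [eye_trace()].
#' @param n_points Number of output points (>= 2). 128 resolves the densest
#'   digit template with more than 10 points per stroke.
#' @return An [eye_trace()] with `n_points` points.
#' @export
resample_equidistant <- function(trace, n_points = 128L) {
  stopifnot(inherits(trace, "eye_trace"))
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) stop_arg("'n_points' must be >= 2")
  p <- trace$points
  seg <- sqrt(rowSums(diff(p)^2))
  total <- sum(seg)
  if (total <= 0) stop_arg("degenerate trace: zero total path length")
  # drop zero-length steps so arc length is strictly increasing
  keep <- c(TRUE, seg > 0)
  p <- p[keep, , drop = FALSE]
  s <- c(0, cumsum(seg[seg > 0]))
  target <- seq(0, total, length.out = n_points)
  out <- cbind(
    approx(s, p[, 1], xout = target)$y,
    approx(s, p[, 2], xout = target)$y
  )
  eye_trace(out, normalized = trace$normalized, meta = trace$meta)
}

#' Normalize a trace to the unit box
#'
#' Independently rescales each axis so the trace spans exactly
#' `[0,1] x [0,1]`; aspect ratio is intentionally not preserved (width and
#' height are both made one). A degenerate axis (zero extent) is centered at
#' 0.5.
#'
#' @param trace An [eye_trace()].
#' @return A normalized [eye_trace()].
#' @export
normalize_box <- function(trace) {
  stopifnot(inherits(trace, "eye_trace"))
  p <- trace$points
  for (k in 1:2) {
    r <- range(p[, k])
    if (diff(r) > 0) {
      p[, k] <- (p[, k] - r[1]) / diff(r)
    } else {
      p[, k] <- 0.5
    }
  }
  eye_trace(p, normalized = TRUE, meta = trace$meta)
}

#' Central finite difference
#'
#' `out[t] = series[t+1] - series[t-1]` for interior points; the output is
#' two samples shorter than the input.
#'
#' @param series Numeric vector of length >= 3.
#' @return Numeric vector of length `length(series) - 2`.
#' @examples
#' finite_difference(c(0, 1, 2, 3))
#' @export
finite_difference <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 3L) stop_arg("need at least 3 samples for a central difference")
  series[3:n] - series[1:(n - 2L)]
}

#' Estimate the horizontal-to-vertical crosstalk coefficient
#'
#' The observed vertical component is modeled as the true vertical component
#' plus `alpha` times the horizontal component. Differentiating both axes
#' with a central finite difference removes levels and drift; `alpha` is then
#' the ordinary least-squares slope of `dy` regressed on `dx` - the unique
#' value for which the compensated differences `dy - alpha * dx` have zero
#' regression slope. No calibration data are required: the estimate uses the
#' epoch's own trace, under the assumption that the intended writing has no
#' net correlation between horizontal and vertical increments (which holds
#' for axis-aligned and stroke-balanced patterns).
#'
#' @param trace A normalized [eye_trace()] with >= 3 points.
#' @return An object of class `crosstalk_model` with `alpha`,
#'   `fit_slope_before` and `fit_slope_after`.
#' @export
estimate_alpha <- function(trace) {
  stopifnot(inherits(trace, "eye_trace"))
  p <- trace$points
  if (nrow(p) < 3L) stop_arg("need at least 3 points to estimate crosstalk")
  dx <- finite_difference(p[, 1])
  dy <- finite_difference(p[, 2])
  vx <- sum((dx - mean(dx))^2)
  if (vx <= 0) stop_arg("cannot estimate crosstalk: no horizontal variation")
  alpha <- sum((dx - mean(dx)) * (dy - mean(dy))) / vx
  resid <- dy - alpha * dx
  after <- sum((dx - mean(dx)) * (resid - mean(resid))) / vx
  structure(
    list(alpha = alpha, fit_slope_before = alpha, fit_slope_after = after),
    class = "crosstalk_model"
  )
}

#' @export
print.crosstalk_model <- function(x, ...) {
  cat(sprintf(
    "<crosstalk_model> alpha = %.4f (difference-space slope %.2e after compensation)\n",
    x$alpha, x$fit_slope_after
  ))
  invisible(x)
}

#' Remove horizontal-to-vertical crosstalk from a trace
#'
#' Replaces each `y` by `y - alpha * x` (the x coordinates are unchanged)
#' and, by default, re-normalizes the result to the unit box.
#'
#' @param trace An [eye_trace()].
#' @param model A `crosstalk_model` from [estimate_alpha()], or a plain
#'   number interpreted as `alpha`.
#' @param renormalize Re-apply [normalize_box()] afterwards (default `TRUE`).
#' @return An [eye_trace()].
#' @export
remove_crosstalk <- function(trace, model, renormalize = TRUE) {
  stopifnot(inherits(trace, "eye_trace"))
  alpha <- if (inherits(model, "crosstalk_model")) model$alpha else as.numeric(model)
  p <- trace$points
  p[, 2] <- p[, 2] - alpha * p[, 1]
  meta <- trace$meta
  meta$alpha <- alpha
  out <- eye_trace(p, normalized = FALSE, meta = meta)
  if (renormalize) normalize_box(out) else out
}

#' Default configuration for trace reconstruction
#'
#' @param target_rate Working sampling rate after downsampling, Hz.
#' @param median_window_ms Median-filter window, ms.
#' @param baseline_ms Pre-epoch baseline window, ms.
#' @param theta Saccade-detection wavelet threshold.
#' @param scale Wavelet scale, samples.
#' @param n_points Points in the resampled trace.
#' @param crosstalk Estimate and remove horizontal-to-vertical crosstalk.
#' @param blink_k,blink_floor_uv,blink_widths_ms Blink-detection parameters,
#'   see [detect_blinks()] and [blink_emphasis_filter()].
#' @return A list of class `reconstruct_config`.
#' @export
reconstruct_config <- function(target_rate = 64, median_window_ms = 31,
                               baseline_ms = 100, theta = 120, scale = 20L,
                               n_points = 128L, crosstalk = TRUE,
                               blink_k = 6, blink_floor_uv = 30,
                               blink_widths_ms = c(100, 150, 200)) {
  structure(
    list(
      target_rate = target_rate, median_window_ms = median_window_ms,
      baseline_ms = baseline_ms, theta = theta, scale = as.integer(scale),
      n_points = as.integer(n_points), crosstalk = isTRUE(crosstalk),
      blink_k = blink_k, blink_floor_uv = blink_floor_uv,
      blink_widths_ms = blink_widths_ms
    ),
    class = "reconstruct_config"
  )
}

#' Reconstruct a normalized eye-writing trace from a raw recording
#'
#' Runs the full ordered pipeline: downsample and median-filter each channel;
#' detect blinks on the vertical bipolar component; remove the pre-epoch
#' baseline per channel; derive the bipolar components; linearly interpolate
#' the blink gaps; remove linear drift; detect saccades by Haar wavelet
#' thresholding; extract the saccadic trace; resample it to equidistant
#' points; normalize to the unit box; and estimate and remove the
#' horizontal-to-vertical crosstalk (followed by re-normalization).
#'
#' @param rec An [eog_recording()].
#' @param cfg A [reconstruct_config()].
#' @param keep_stages Also return the intermediate artifacts (downsampled
#'   recording, blink table, bipolar signal, saccade mask, raw trace,
#'   crosstalk model).
#' @return An [eye_trace()]; with `keep_stages = TRUE`, a list with elements
#'   `trace` and `stages`.
#' @export
reconstruct <- function(rec, cfg = reconstruct_config(), keep_stages = FALSE) {
  stopifnot(inherits(rec, "eog_recording"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_arg("reconstruction failed at stage '", name, "': ", conditionMessage(e))
    })
  }
  ds <- stage("downsample", {
    r <- if (rec$rate > cfg$target_rate) downsample(rec, cfg$target_rate) else rec
    w <- odd_window(cfg$median_window_ms, r$rate)
    r$samples <- apply(r$samples, 2L, median_filter, window = w)
    r
  })
  blinks <- stage("blink_detection", {
    v_tmp <- channel(ds, "above") - channel(ds, "below")
    detect_blinks(
      blink_emphasis_filter(v_tmp, ds$rate, cfg$blink_widths_ms),
      k = cfg$blink_k, floor_uv = cfg$blink_floor_uv
    )
  })
  ds <- stage("baseline", {
    ds$samples <- apply(ds$samples, 2L, remove_baseline,
      rate = ds$rate, pre_window_ms = cfg$baseline_ms
    )
    ds
  })
  bip <- stage("bipolar", derive_bipolar(ds))
  bip <- stage("blink_interpolation", interpolate_blinks(bip, blinks))
  bip <- stage(
    "drift",
    bipolar_signal(remove_drift(bip$h), remove_drift(bip$v), bip$rate)
  )
  mask <- stage("saccade_detection", {
    detect_saccades(bip, threshold = cfg$theta, scale = cfg$scale)
  })
  tr <- stage("extract", extract_trace(bip, mask))
  extent <- apply(tr$points, 2L, function(z) diff(range(z)))
  tr <- stage("resample", resample_equidistant(tr, cfg$n_points))
  tr <- stage("normalize", normalize_box(tr))
  model <- NULL
  if (cfg$crosstalk) {
    model <- stage("crosstalk", estimate_alpha(tr))
    tr <- stage("crosstalk", remove_crosstalk(tr, model))
    # alpha is estimated in unit-box coordinates; rescaling by the raw
    # vertical/horizontal extent ratio expresses it in signal units
    if (extent[1] > 0) {
      tr$meta$alpha_physical <- model$alpha * extent[2] / extent[1]
    }
  }
  tr$meta$n_blinks <- nrow(blinks)
  if (!is.null(rec$meta$digit)) tr$meta$digit <- rec$meta$digit
  if (!is.null(rec$meta$participant)) tr$meta$participant <- rec$meta$participant
  if (!keep_stages) {
    return(tr)
  }
  list(
    trace = tr,
    stages = list(
      downsampled = ds, blinks = blinks, bipolar = bip,
      mask = mask, crosstalk = model
    )
  )
}
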