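# Preprocessing: downsampling, median filtering, blink detection/removal,
# baseline removal, bipolar derivation, blink-gap interpolation, drift
# removal. These are the six conditioning steps applied to a raw recording
# before saccade detection.

#' Downsample a recording with anti-aliasing
#'
#' Applies a zero-phase FIR low-pass (windowed-sinc, cutoff at 90% of the
#' target Nyquist) before decimation, so mains and EMG noise cannot alias
#' into the band of interest. Integer rate ratios decimate by striding;
#' rational ratios are resampled on the filtered signal.
#'
#' @param rec An [eog_recording()].
#' @param target_rate Target sampling rate in Hz; must be below `rec$rate`.
#' @return An [eog_recording()] at `target_rate` with the same channel roles.
#' @export
downsample <- function(rec, target_rate = 64) {
  stopifnot(inherits(rec, "eog_recording"))
  if (!is.numeric(target_rate) || target_rate <= 0) {
    stop_arg("'target_rate' must be positive")
  }
  if (target_rate >= rec$rate) {
    stop_arg("'target_rate' must be below the recording rate (", rec$rate, " Hz)")
  }
  out <- apply(rec$samples, 2L, decimate_1d,
    rate = rec$rate, target_rate = target_rate
  )
  eog_recording(out, target_rate, channels = rec$channels, meta = rec$meta)
}

decimate_1d <- function(x, rate, target_rate) {
  n <- length(x)
  q <- rate / target_rate
  # FIR order ~ 10 taps per decimation unit, capped for short signals
  ord <- min(2L * floor(5 * q), 2L * floor((n - 2L) / 6))
  ord <- max(ord, 4L)
  b <- signal::fir1(ord, 0.9 / q)
  b <- b / sum(b) # exact unit DC gain
  # reflect the ends so the zero-phase filter has no start-up transients
  p <- min(ord, n - 1L)
  padded <- c(rev(x[seq_len(p)]), x, rev(x[seq.int(n - p + 1L, n)]))
  y <- as.numeric(signal::filtfilt(signal::Ma(b), padded))[p + seq_len(n)]
  if (abs(q - round(q)) < 1e-9) {
    y[seq(1L, n, by = as.integer(round(q)))]
  } else {
    t_new <- seq(0, (n - 1) / rate, by = 1 / target_rate)
    approx(x = (seq_len(n) - 1) / rate, y = y, xout = t_new)$y
  }
}

#' Sliding median filter
#'
#' Removes impulsive high-frequency noise while preserving step edges.
#' Edges are handled by reflecting the signal.
#'
#' @param signal Numeric vector.
#' @param window Odd window length in samples.
#' @return Filtered vector of the same length.
#' @examples
#' median_filter(c(0, 0, 100, 0, 0), 3)
#' @export
median_filter <- function(signal, window = 3L) {
  signal <- as.numeric(signal)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop_arg("'window' must be an odd positive sample count")
  }
  if (window == 1L || length(signal) <= 2L) {
    return(signal)
  }
  h <- (window - 1L) %/% 2L
  padded <- c(rev(signal[seq_len(min(h, length(signal)))]),
    signal,
    rev(signal[seq.int(length(signal) - min(h, length(signal)) + 1L, length(signal))])
  )
  sm <- stats::runmed(padded, window, endrule = "keep")
  sm[(h + 1L):(h + length(signal))]
}

#' Blink-emphasizing filter
#'
#' A multi-scale bank of paired moving-average differences: at each scale the
#' output is the mean over the window just after a sample minus the mean over
#' the window just before it, i.e. a smoothed edge detector. The scale with
#' the largest absolute response is returned. A blink bump produces a
#' pronounced local maximum (rising lid) followed by a local minimum (falling
#' lid); slow drift yields a small, nearly constant response.
#'
#' @param signal Vertical-channel (or vertical bipolar) series, microvolts.
#' @param rate Sampling rate in Hz.
#' @param widths_ms Candidate window widths in ms, around the half-duration
#'   of a typical blink.
#' @return An object of class `blink_filter` with elements `values` (filtered
#'   series, same length), `width` (chosen window, samples), `width_ms`,
#'   `rate`, and `signal` (the input, retained for downstream vetting of
#'   candidate intervals).
#' @export
blink_emphasis_filter <- function(signal, rate, widths_ms = c(100, 150, 200)) {
  signal <- as.numeric(signal)
  best <- NULL
  for (wm in widths_ms) {
    w <- max(1L, round(wm / 1000 * rate))
    vals <- edge_response(signal, w)
    if (is.null(best) || max(abs(vals)) > max(abs(best$values))) {
      best <- list(values = vals, width = w, width_ms = wm)
    }
  }
  structure(
    list(
      values = best$values, width = best$width, width_ms = best$width_ms,
      rate = rate, signal = signal
    ),
    class = "blink_filter"
  )
}

# mean(x[t+1 .. t+w]) - mean(x[t-w+1 .. t]) with reflection padding
edge_response <- function(x, w) {
  n <- length(x)
  if (n < 2L) {
    return(rep(0, n))
  }
  wp <- min(w, n - 1L)
  pad <- c(rev(x[seq_len(wp)]), x, rev(x[seq.int(n - wp + 1L, n)]))
  cs <- cumsum(c(0, pad))
  i <- seq_len(n) + wp # position of t in padded coordinates
  after <- (cs[i + wp + 1L] - cs[i + 1L]) / wp
  before <- (cs[i + 1L] - cs[i - wp + 1L]) / wp
  after - before
}

#' Detect eye-blink intervals
#'
#' Works on the output of [blink_emphasis_filter()]. Candidate blinks are
#' local maxima of the filtered series paired with the nearest following
#' local minimum (within `max_pair_gap_ms`), both exceeding an adaptive
#' amplitude threshold (`k` times the MAD of the filtered series, with an
#' absolute floor). Each surviving pair initially spans the interval from
#' the maximum minus the filter width to the minimum plus the filter width,
#' and is then trimmed to the blink's measured support (the region around
#' the apex where the signal deviates from the local baseline), so that the
#' excision does not swallow neighbouring saccades. Because the
#' eyelid returns to its resting position, a blink's excursion dominates
#' whatever gaze-level change happens underneath it, so the net pre-to-post
#' level shift stays well below the peak excursion; for a saccade sequence
#' masquerading as a blink the two are comparable. Candidates whose level
#' shift exceeds `return_frac` of the peak excursion are therefore rejected
#' as eye movements rather than blinks. A second veto uses dwell time: a
#' blink is transient, spending only about a third of its duration near its
#' apex, whereas a saccade-fixation-saccade excursion holds its apex level
#' for a full fixation; candidates dwelling near the apex for longer than
#' `dwell_max_ms` are rejected.
#'
#' @param filtered A `blink_filter` object.
#' @param k Multiplier on the MAD of the filtered series (adaptive threshold).
#' @param floor_uv Absolute lower bound on the threshold, microvolts, so a
#'   noise-free recording does not degenerate to a zero threshold.
#' @param max_pair_gap_ms Maximum time from a local maximum to its paired
#'   minimum.
#' @param return_frac Maximum |post - pre| baseline shift, as a fraction of
#'   the peak excursion, for a candidate to count as a blink.
#' @param dwell_max_ms Maximum time the signal may spend above 70% of the
#'   apex deviation for a candidate to count as a blink.
#' @return A data frame with one row per blink: `start`, `end`, `peak`
#'   (sample indices, start <= peak <= end). Zero rows when no blinks.
#' @export
detect_blinks <- function(filtered, k = 6, floor_uv = 30,
                          max_pair_gap_ms = 500, return_frac = 0.85,
                          dwell_max_ms = 150) {
  stopifnot(inherits(filtered, "blink_filter"))
  f <- filtered$values
  n <- length(f)
  empty <- data.frame(start = integer(0), end = integer(0), peak = integer(0))
  if (n < 3L) {
    return(empty)
  }
  thr <- max(k * mad(f), floor_uv)
  ext <- local_extrema(f)
  maxima <- ext$max[f[ext$max] > thr]
  minima <- ext$min[f[ext$min] < -thr]
  if (!length(maxima) || !length(minima)) {
    return(empty)
  }
  gap <- round(max_pair_gap_ms / 1000 * filtered$rate)
  w <- filtered$width
  sig <- filtered$signal
  out <- empty
  used_max <- rep(FALSE, length(maxima))
  for (mn in minima) {
    cand <- which(!used_max & maxima < mn & maxima >= mn - gap)
    if (!length(cand)) next
    j <- cand[length(cand)] # nearest preceding maximum
    mx <- maxima[j]
    start <- max(1L, mx - w)
    end <- min(n, mn + w)
    # baseline-return vetting on the underlying signal; short reference
    # windows (~80 ms) read the local level without straddling the
    # neighbouring strokes of densely written digits
    g <- max(3L, round(0.08 * filtered$rate))
    pre <- median(sig[max(1L, start - g):start])
    post <- median(sig[end:min(n, end + g)])
    dev <- abs(sig[start:end] - pre)
    excursion <- max(dev)
    if (excursion <= 0 || abs(post - pre) > return_frac * excursion) next
    dwell <- sum(dev > 0.7 * excursion) / filtered$rate * 1000
    if (dwell > dwell_max_ms) next
    used_max[j] <- TRUE
    peak <- start + which.max(dev) - 1L
    # trim the interval to the blink's support: walk outward from the apex
    # until the signal rejoins the local baseline on each side, so the
    # excision does not swallow neighbouring saccades
    lo <- peak
    while (lo > 1L && abs(sig[lo - 1L] - pre) > 0.15 * excursion) lo <- lo - 1L
    exc_r <- abs(sig[peak] - post)
    hi <- peak
    while (hi < end && exc_r > 0 && abs(sig[hi + 1L] - post) > 0.15 * exc_r) hi <- hi + 1L
    start <- max(start, lo - 2L)
    end <- min(end, hi + 2L)
    out <- rbind(out, data.frame(start = start, end = end, peak = peak))
  }
  if (nrow(out) <= 1L) {
    return(out)
  }
  # merge overlapping intervals, keeping the larger-excursion peak
  out <- out[order(out$start), , drop = FALSE]
  merged <- out[1L, , drop = FALSE]
  for (i in 2:nrow(out)) {
    last <- nrow(merged)
    if (out$start[i] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], out$end[i])
      pre <- median(sig[max(1L, merged$start[last] - w):merged$start[last]])
      seg <- merged$start[last]:merged$end[last]
      merged$peak[last] <- seg[which.max(abs(sig[seg] - pre))]
    } else {
      merged <- rbind(merged, out[i, , drop = FALSE])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Remove the pre-epoch baseline from a signal
#'
#' Subtracts the median of the data immediately preceding the writing epoch.
#' When no epoch start is given, the first `pre_window_ms` of the record are
#' used as the preceding data.
#'
#' @param signal Numeric vector.
#' @param rate Sampling rate in Hz.
#' @param pre_window_ms Length of the baseline window, ms.
#' @param epoch_start Optional sample index at which writing starts; the
#'   window then ends just before it.
#' @return `signal` minus its baseline median.
#' @export
remove_baseline <- function(signal, rate, pre_window_ms = 100, epoch_start = NULL) {
  signal <- as.numeric(signal)
  w <- max(1L, round(pre_window_ms / 1000 * rate))
  if (is.null(epoch_start)) {
    if (length(signal) < w) stop_arg("signal shorter than the baseline window")
    win <- signal[seq_len(w)]
  } else {
    epoch_start <- as.integer(epoch_start)
    if (epoch_start <= w) stop_arg("not enough samples before 'epoch_start'")
    win <- signal[(epoch_start - w):(epoch_start - 1L)]
  }
  signal - median(win)
}

#' Derive bipolar horizontal/vertical EOG components
#'
#' Horizontal = right - left; vertical = above - below. The subtraction
#' cancels common-mode potentials shared by the paired electrodes.
#'
#' @param rec An [eog_recording()] with all four roles mapped.
#' @return A [bipolar_signal()].
#' @export
derive_bipolar <- function(rec) {
  stopifnot(inherits(rec, "eog_recording"))
  bipolar_signal(
    h = channel(rec, "right") - channel(rec, "left"),
    v = channel(rec, "above") - channel(rec, "below"),
    rate = rec$rate
  )
}

#' Interpolate over blink intervals
#'
#' Replaces the samples inside each blink interval (on both bipolar
#' components) with the straight line joining the last sample before and the
#' first sample after the interval. Intervals touching a signal boundary hold
#' the nearest valid value.
#'
#' @param sig A [bipolar_signal()].
#' @param blinks Data frame of blink intervals from [detect_blinks()] (columns
#'   `start`, `end`).
#' @return A [bipolar_signal()] with blink gaps filled.
#' @export
interpolate_blinks <- function(sig, blinks) {
  stopifnot(inherits(sig, "bipolar_signal"))
  if (is.null(blinks) || nrow(blinks) == 0L) {
    return(sig)
  }
  n <- length(sig$h)
  if (any(blinks$start < 1L) || any(blinks$end > n) || any(blinks$start > blinks$end)) {
    stop_arg("blink intervals out of range")
  }
  fill <- function(x) {
    for (i in seq_len(nrow(blinks))) {
      s <- blinks$start[i]
      e <- blinks$end[i]
      left <- if (s > 1L) x[s - 1L] else NA_real_
      right <- if (e < n) x[e + 1L] else NA_real_
      if (is.na(left) && is.na(right)) next
      if (is.na(left)) left <- right # hold nearest valid value at boundary
      if (is.na(right)) right <- left
      k <- e - s + 2L
      x[s:e] <- left + (right - left) * seq_len(e - s + 1L) / k
    }
    x
  }
  bipolar_signal(fill(sig$h), fill(sig$v), sig$rate)
}

#' Remove low-frequency linear drift
#'
#' Subtracts the ordinary least-squares line fitted over the whole epoch, so
#' the output has exactly zero linear trend.
#'
#' @param signal Numeric vector of length >= 2.
#' @return Detrended vector of the same length.
#' @export
remove_drift <- function(signal) {
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n < 2L) stop_arg("need at least 2 samples to fit a drift line")
  t <- seq_len(n)
  tc <- t - mean(t)
  slope <- sum(tc * signal) / sum(tc^2)
  signal - (mean(signal) + slope * tc)
}
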