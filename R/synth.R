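# Ground-truth-annotated synthetic EOG: four periocular channels tracing the
# digit templates with sigmoid saccades, fixations, per-channel baseline
# offsets, linear drift, Gaussian noise, raised-cosine blinks, and a
# controllable horizontal-to-vertical crosstalk coefficient. Every pipeline
# stage can be validated against the emitted ground truth.

#' Configuration for the synthetic EOG generator
#'
#' Defaults emulate a typical acquisition: 2048 Hz sampling, roughly 80
#' microvolts of EOG deflection per grid unit of gaze displacement, 60-ms
#' saccades with a sigmoid position profile, 250-ms inter-stroke fixations,
#' 5-microvolt sensor noise, a few microvolts per second of electrode drift,
#' and occasional 300-microvolt, 300-ms blinks.
#'
#' @param rate Sampling rate, Hz.
#' @param amplitude_per_unit EOG amplitude per grid unit, microvolts.
#' @param saccade_duration_ms Saccade duration (sigmoid 1-99% rise), ms.
#' @param fixation_ms Fixation between strokes, ms.
#' @param lead_ms,tail_ms Fixation before the first and after the last
#'   stroke, ms. The 3-s lead mirrors the writing protocol, in which the
#'   participant holds a fixation mark for three seconds before writing; it
#'   also provides the pre-epoch baseline window and anchors the linear
#'   drift fit on stationary data.
#' @param noise_sd_uv Gaussian noise SD per channel, microvolts.
#' @param drift_uv_per_s Maximum magnitude of the per-channel linear drift
#'   slope (drawn uniformly in +/- this value), microvolts per second.
#' @param blink_rate_per_epoch Expected blinks per epoch (Poisson).
#' @param blink_amp_uv Blink amplitude on the above-eye channel, microvolts.
#' @param blink_dur_ms Blink duration, ms.
#' @param alpha Injected horizontal-to-vertical crosstalk coefficient.
#' @param baseline_offsets_uv Named numeric: constant electrode offsets for
#'   `left`, `right`, `above`, `below`, microvolts.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(rate = 2048, amplitude_per_unit = 80,
                         saccade_duration_ms = 60, fixation_ms = 250,
                         lead_ms = 3000, tail_ms = 500,
                         noise_sd_uv = 5, drift_uv_per_s = 3,
                         blink_rate_per_epoch = 0.5, blink_amp_uv = 300,
                         blink_dur_ms = 300, alpha = 0,
                         baseline_offsets_uv = c(
                           left = 12, right = -8, above = 15, below = -10
                         )) {
  cfg <- list(
    rate = rate, amplitude_per_unit = amplitude_per_unit,
    saccade_duration_ms = saccade_duration_ms, fixation_ms = fixation_ms,
    lead_ms = lead_ms, tail_ms = tail_ms,
    noise_sd_uv = noise_sd_uv, drift_uv_per_s = drift_uv_per_s,
    blink_rate_per_epoch = blink_rate_per_epoch,
    blink_amp_uv = blink_amp_uv, blink_dur_ms = blink_dur_ms,
    alpha = alpha, baseline_offsets_uv = baseline_offsets_uv
  )
  pos <- c(
    "rate", "amplitude_per_unit", "saccade_duration_ms", "fixation_ms",
    "lead_ms", "tail_ms", "blink_amp_uv", "blink_dur_ms"
  )
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stop_arg("'", f, "' must be > 0")
  }
  for (f in c("noise_sd_uv", "drift_uv_per_s", "blink_rate_per_epoch")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) stop_arg("'", f, "' must be >= 0")
  }
  if (!all(c("left", "right", "above", "below") %in% names(cfg$baseline_offsets_uv))) {
    stop_arg("'baseline_offsets_uv' must name all four channels")
  }
  structure(cfg, class = "synth_config")
}

# Sigmoid position profile from 0 to 1 over n samples, pinned to the
# endpoints so saccades start and land exactly on the waypoints.
sigmoid_profile <- function(n) {
  if (n <= 1L) {
    return(rep(1, max(n, 0L)))
  }
  u <- seq(0, 1, length.out = n)
  s <- 1 / (1 + exp(-12 * (u - 0.5)))
  (s - s[1]) / (s[n] - s[1])
}

#' Simulate one eye-writing epoch
#'
#' The gaze steps through the template waypoints with sigmoid saccades
#' separated by fixations. The ideal horizontal and vertical EOG components
#' are the amplitude-scaled gaze coordinates; the emitted vertical component
#' additionally receives `alpha` times the horizontal one (the crosstalk the
#' pipeline must remove). The four channels split each component
#' symmetrically (`right = +h/2`, `left = -h/2`, `above = +v/2`,
#' `below = -v/2`) on top of their electrode offsets, then per-channel linear
#' drift, Gaussian noise, and Poisson-placed blinks (a raised-cosine bump on
#' the above-eye channel with a 20% negative counterpart below) are applied.
#'
#' @param tpl A [digit_template()].
#' @param cfg A [synth_config()].
#' @param seed Integer seed; fixes all randomness of the epoch.
#' @return A list with `recording` (an [eog_recording()]) and `truth`: digit
#'   label, gaze path in grid units (`t`, `x`, `y`), `saccades` (data frame
#'   of onset/offset sample indices and times), `blinks` (start/end/peak
#'   sample indices), injected `alpha`, and the drawn drift slopes.
#' @export
simulate_epoch <- function(tpl, cfg = synth_config(), seed = 1L) {
  stopifnot(inherits(tpl, "digit_template"), inherits(cfg, "synth_config"))
  with_seed(seed, {
    rate <- cfg$rate
    ms <- function(d) max(1L, round(d / 1000 * rate))
    n_lead <- ms(cfg$lead_ms)
    n_sac <- ms(cfg$saccade_duration_ms)
    n_fix <- ms(cfg$fixation_ms)
    n_tail <- ms(cfg$tail_ms)
    wp <- tpl$waypoints
    k <- nrow(wp)

    x <- rep(wp[1, 1], n_lead)
    y <- rep(wp[1, 2], n_lead)
    onsets <- integer(0)
    offsets <- integer(0)
    for (i in seq_len(k - 1L)) {
      prof <- sigmoid_profile(n_sac)
      onsets <- c(onsets, length(x) + 1L)
      x <- c(x, wp[i, 1] + (wp[i + 1L, 1] - wp[i, 1]) * prof)
      y <- c(y, wp[i, 2] + (wp[i + 1L, 2] - wp[i, 2]) * prof)
      offsets <- c(offsets, length(x))
      n_hold <- if (i < k - 1L) n_fix else n_tail
      x <- c(x, rep(wp[i + 1L, 1], n_hold))
      y <- c(y, rep(wp[i + 1L, 2], n_hold))
    }
    x <- unname(x)
    y <- unname(y)
    n <- length(x)
    t <- (seq_len(n) - 1L) / rate

    amp <- cfg$amplitude_per_unit
    h_ideal <- amp * x
    v_ideal <- amp * y
    v_emit <- v_ideal + cfg$alpha * h_ideal

    off <- cfg$baseline_offsets_uv
    chans <- cbind(
      left = -h_ideal / 2 + off[["left"]],
      right = h_ideal / 2 + off[["right"]],
      above = v_emit / 2 + off[["above"]],
      below = -v_emit / 2 + off[["below"]]
    )

    slopes <- runif(4L, -cfg$drift_uv_per_s, cfg$drift_uv_per_s)
    chans <- chans + outer(t, slopes)

    n_blinks <- rpois(1L, cfg$blink_rate_per_epoch)
    blink_tab <- data.frame(start = integer(0), end = integer(0), peak = integer(0))
    if (n_blinks > 0L) {
      half <- ms(cfg$blink_dur_ms) %/% 2L
      lo <- half + 1L
      hi <- n - half
      centers <- integer(0)
      for (b in seq_len(n_blinks)) {
        for (try in 1:20) {
          cand <- sample.int(hi - lo + 1L, 1L) + lo - 1L
          if (!length(centers) || min(abs(centers - cand)) > rate) {
            centers <- c(centers, cand)
            break
          }
        }
      }
      for (cc in sort(centers)) {
        idx <- (cc - half):(cc + half)
        bump <- cfg$blink_amp_uv * 0.5 *
          (1 + cos(pi * (idx - cc) / half))
        chans[idx, "above"] <- chans[idx, "above"] + bump
        chans[idx, "below"] <- chans[idx, "below"] - 0.2 * bump
        blink_tab <- rbind(
          blink_tab,
          data.frame(start = idx[1], end = idx[length(idx)], peak = cc)
        )
      }
    }

    if (cfg$noise_sd_uv > 0) {
      chans <- chans + matrix(rnorm(n * 4L, sd = cfg$noise_sd_uv), n, 4L)
    }

    rec <- eog_recording(
      chans, rate,
      channels = c(left = 1L, right = 2L, above = 3L, below = 4L),
      meta = list(digit = tpl$label, seed = seed)
    )
    truth <- list(
      digit = tpl$label,
      t = t, x = x, y = y,
      saccades = data.frame(
        onset = onsets, offset = offsets,
        onset_s = (onsets - 1L) / rate, offset_s = (offsets - 1L) / rate
      ),
      blinks = blink_tab,
      alpha = cfg$alpha,
      drift_slopes = slopes
    )
    list(recording = rec, truth = truth)
  })
}

#' Simulate a cohort of eye-writing participants
#'
#' Draws subject-level parameters once per participant (uniform jitter
#' around the base configuration: amplitude and stroke timing +/- 20%, noise
#' +/- 30%, crosstalk alpha uniform in +/- 0.2), then simulates
#' `trials_per_digit` epochs of every digit for each participant. All
#' randomness derives deterministically from `seed`.
#'
#' @param n_participants Number of simulated participants (>= 1).
#' @param trials_per_digit Writing repetitions per digit.
#' @param cfg_base Base [synth_config()].
#' @param seed Master seed.
#' @param jitter Apply subject-level parameter jitter (`FALSE` makes all
#'   subjects identical to `cfg_base` apart from epoch-level noise).
#' @param templates Template set (default: built-in).
#' @param dir Optional directory: recordings are written as CSV with a
#'   `manifest.csv` and a `ground_truth.json` sidecar.
#' @return A list with `index` (data frame: participant, trial, digit),
#'   `recordings`, `truth` (parallel lists), and `subject_params`.
#' @export
simulate_cohort <- function(n_participants = 18L, trials_per_digit = 3L,
                            cfg_base = synth_config(), seed = 1L,
                            jitter = TRUE, templates = builtin_templates(),
                            dir = NULL) {
  stopifnot(n_participants >= 1L, trials_per_digit >= 1L)
  subject_params <- lapply(seq_len(n_participants), function(s) {
    with_seed(child_seed(seed, s, 0L, 0L), {
      if (jitter) {
        list(
          amplitude_per_unit = cfg_base$amplitude_per_unit * runif(1, 0.8, 1.2),
          alpha = runif(1, -0.2, 0.2),
          noise_sd_uv = cfg_base$noise_sd_uv * runif(1, 0.7, 1.3),
          saccade_duration_ms = cfg_base$saccade_duration_ms * runif(1, 0.8, 1.2),
          fixation_ms = cfg_base$fixation_ms * runif(1, 0.8, 1.2)
        )
      } else {
        list(
          amplitude_per_unit = cfg_base$amplitude_per_unit,
          alpha = cfg_base$alpha,
          noise_sd_uv = cfg_base$noise_sd_uv,
          saccade_duration_ms = cfg_base$saccade_duration_ms,
          fixation_ms = cfg_base$fixation_ms
        )
      }
    })
  })
  index <- data.frame()
  recordings <- list()
  truths <- list()
  for (s in seq_len(n_participants)) {
    cfg_s <- cfg_base
    for (f in names(subject_params[[s]])) cfg_s[[f]] <- subject_params[[s]][[f]]
    for (trial in seq_len(trials_per_digit)) {
      for (digit in 0:9) {
        ep <- simulate_epoch(
          templates[[digit + 1L]], cfg_s,
          seed = child_seed(seed, s, trial, digit + 1L)
        )
        pid <- sprintf("S%02d", s)
        ep$recording$meta$participant <- pid
        ep$recording$meta$trial <- trial
        index <- rbind(
          index,
          data.frame(participant = pid, trial = trial, digit = digit)
        )
        recordings[[length(recordings) + 1L]] <- ep$recording
        truths[[length(truths) + 1L]] <- ep$truth
      }
    }
  }
  out <- list(
    index = index, recordings = recordings, truth = truths,
    subject_params = subject_params
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(nrow(index))
    for (i in seq_len(nrow(index))) {
      paths[i] <- sprintf(
        "%s_t%d_d%d.csv", index$participant[i], index$trial[i], index$digit[i]
      )
      write_recording(recordings[[i]], file.path(dir, paths[i]))
    }
    manifest <- cbind(index, path = paths)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(truths, function(tr) tr[c("digit", "saccades", "blinks", "alpha")]),
      file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
    out$dir <- dir
    out$manifest <- manifest
  }
  out
}

#' Simulate a skewed writing trace
#'
#' Produces a normalized trace with a known injected horizontal-to-vertical
#' crosstalk: starting from a template trace (or a random rectilinear
#' polyline on the writing grid), each `y` becomes `y + alpha * x`, and
#' Gaussian noise is added to both coordinates. Rectilinear shapes have
#' axis-aligned strokes, so their horizontal and vertical increments are
#' uncorrelated and the injected `alpha` is identifiable from the trace
#' alone - the regime the calibration-free estimator is designed for.
#'
#' @param shape A [digit_template()], or `"random"` for a random rectilinear
#'   polyline.
#' @param alpha Injected crosstalk coefficient.
#' @param noise_sd Coordinate noise SD, in unit-box units.
#' @param n_points Points in the trace.
#' @param seed Integer seed.
#' @return An [eye_trace()] (not re-normalized after injection, so the
#'   injected coefficient is recoverable exactly in the noiseless limit).
#' @export
simulate_skewed_trace <- function(shape = "random", alpha = 0, noise_sd = 0.01,
                                  n_points = 128L, seed = 1L) {
  with_seed(seed, {
    if (inherits(shape, "digit_template")) {
      base <- template_trace(shape, n_points)
    } else if (identical(shape, "random")) {
      # random Manhattan path on the 3 x 3 lattice, 5-8 strokes
      k <- sample(5:8, 1L)
      pos <- c(sample(0:2, 1L), sample(0:2, 1L))
      wp <- matrix(pos, 1L, 2L)
      axis <- sample(1:2, 1L)
      for (i in seq_len(k)) {
        repeat {
          step <- sample(c(-2L, -1L, 1L, 2L), 1L)
          cand <- pos
          cand[axis] <- pos[axis] + step
          if (cand[axis] >= 0L && cand[axis] <= 2L) break
        }
        pos <- cand
        wp <- rbind(wp, pos)
        axis <- 3L - axis
      }
      base <- normalize_box(resample_equidistant(eye_trace(wp), n_points))
    } else {
      stop_arg("'shape' must be a digit_template or \"random\"")
    }
    p <- base$points
    p[, 2] <- p[, 2] + alpha * p[, 1]
    if (noise_sd > 0) p <- p + matrix(rnorm(length(p), sd = noise_sd), ncol = 2L)
    eye_trace(p, normalized = FALSE, meta = list(alpha_true = alpha))
  })
}
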