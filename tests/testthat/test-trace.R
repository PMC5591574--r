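# Trace extraction, resampling, normalization, finite differences,
# crosstalk estimation/removal, and the full reconstruction pipeline.

test_that("trace extraction keeps exactly the saccadic samples in order", {
  n <- 20
  sig <- bipolar_signal(1:n, (1:n)^2, 64)
  all_on <- saccade_mask(rep(TRUE, n), 10)
  tr <- extract_trace(sig, all_on)
  expect_equal(tr$points[, 1], as.numeric(1:n))

  m <- rep(FALSE, n)
  m[3:7] <- TRUE
  m[12:16] <- TRUE
  tr2 <- extract_trace(sig, saccade_mask(m, 10))
  expect_equal(nrow(tr2$points), 10L)
  expect_equal(tr2$points[, 1], as.numeric(c(3:7, 12:16)))

  expect_error(extract_trace(sig, saccade_mask(rep(FALSE, n), 10)), "degenerate")
  expect_error(extract_trace(sig, saccade_mask(rep(TRUE, 5), 10)), "match")
})

test_that("equidistant resampling spaces points uniformly on the polyline", {
  seg <- eye_trace(cbind(c(0, 1), c(0, 0)))
  out <- resample_equidistant(seg, 5)
  expect_equal(out$points[, 1], c(0, .25, .5, .75, 1))
  expect_equal(out$points[, 2], rep(0, 5))

  lshape <- eye_trace(cbind(c(0, 1, 1), c(0, 0, 1))) # total length 2
  out2 <- resample_equidistant(lshape, 5)
  gaps <- sqrt(rowSums(diff(out2$points)^2))
  expect_equal(gaps, rep(0.5, 4), tolerance = 1e-9)
  expect_equal(out2$points[1, ], c(x = 0, y = 0))
  expect_equal(out2$points[5, ], c(x = 1, y = 1))

  # idempotence on an already-equidistant trace
  out3 <- resample_equidistant(out2, 5)
  expect_equal(out3$points, out2$points, tolerance = 1e-9)

  expect_error(resample_equidistant(eye_trace(cbind(c(1, 1), c(2, 2))), 8), "degenerate")
})

test_that("resampling preserves digit-polyline length within 1% at n >= 64", {
  # resampling cuts corners, so the loss bound scales with point density:
  # sharp-cornered patterns (the digit-3 pinch, the digit-8 crossing) set
  # the worst case at each density, reaching the sub-1% regime by n = 256
  bounds <- c("64" = 0.025, "128" = 0.0125, "256" = 0.01)
  for (tpl in builtin_templates()) {
    tr <- eye_trace(tpl$waypoints)
    len0 <- sum(sqrt(rowSums(diff(tr$points)^2)))
    for (n in c(64L, 128L, 256L)) {
      out <- resample_equidistant(tr, n)
      len1 <- sum(sqrt(rowSums(diff(out$points)^2)))
      expect_lt(abs(len1 - len0) / len0, bounds[[as.character(n)]])
    }
  }
})

test_that("box normalization spans the unit square and is idempotent", {
  tr <- eye_trace(cbind(c(2, 3, 4), c(10, 20, 15)))
  out <- normalize_box(tr)
  expect_equal(range(out$points[, 1]), c(0, 1))
  expect_equal(range(out$points[, 2]), c(0, 1))
  expect_true(out$normalized)
  expect_equal(normalize_box(out)$points, out$points)

  # aspect ratio intentionally not preserved: 10 x 1 box -> unit square
  wide <- normalize_box(eye_trace(cbind(c(0, 10, 10, 0), c(0, 0, 1, 1))))
  expect_equal(diff(range(wide$points[, 1])), 1)
  expect_equal(diff(range(wide$points[, 2])), 1)

  # degenerate axis centers at 0.5
  flat <- normalize_box(eye_trace(cbind(c(0, 1, 2), c(3, 3, 3))))
  expect_equal(flat$points[, 2], rep(0.5, 3))

  # translation/scale invariance
  p <- random_trace(20, 7)$points
  for (a in c(0.5, 4)) {
    shifted <- eye_trace(a * p + 13)
    expect_equal(normalize_box(shifted)$points, normalize_box(eye_trace(p))$points)
  }
})

test_that("central finite difference matches its definition", {
  expect_equal(finite_difference(c(0, 1, 2, 3)), c(2, 2))
  expect_equal(finite_difference(rep(7, 10)), rep(0, 8))
  x <- with_test_seed(8, rnorm(50))
  loop <- vapply(2:49, function(t) x[t + 1] - x[t - 1], numeric(1))
  expect_equal(finite_difference(x), loop)
  expect_error(finite_difference(c(1, 2)), "3 samples")
})

test_that("crosstalk estimation recovers forced and injected coefficients", {
  # v = h exactly forces alpha = 1
  t <- seq(0, 1, length.out = 50)
  ident <- eye_trace(cbind(t + 0.1 * sin(9 * t), t + 0.1 * sin(9 * t)))
  m <- estimate_alpha(ident)
  expect_equal(m$alpha, 1)
  expect_lt(abs(m$fit_slope_after), 1e-9)

  # symmetric strokes, independent axes: alpha near 0
  rect <- template_trace(builtin_templates()[[1]]) # rectangle digit 0
  expect_lt(abs(estimate_alpha(rect)$alpha), 0.05)

  # injected mixing recovered within the Monte-Carlo band
  sk <- simulate_skewed_trace("random", alpha = 0.30, noise_sd = 0.01, seed = 21)
  expect_true(estimate_alpha(sk)$alpha > 0.25 && estimate_alpha(sk)$alpha < 0.35)

  vline <- eye_trace(cbind(rep(0, 10), seq(0, 1, length.out = 10)))
  expect_error(estimate_alpha(vline), "horizontal variation")
})

test_that("crosstalk removal compensates and reaches a fixed point", {
  tr <- random_trace(40, 9)
  expect_equal(remove_crosstalk(tr, 0, renormalize = FALSE)$points, tr$points)

  t <- seq(0, 1, length.out = 30)
  shape <- t + 0.2 * sin(7 * t)
  same <- eye_trace(cbind(shape, shape))
  comp <- remove_crosstalk(same, 1, renormalize = FALSE)
  expect_equal(diff(range(comp$points[, 2])), 0) # compensated v constant

  sk <- simulate_skewed_trace("random", alpha = -0.35, noise_sd = 0.01, seed = 31)
  fitted <- estimate_alpha(sk)
  out <- remove_crosstalk(sk, fitted, renormalize = FALSE)
  expect_lt(abs(estimate_alpha(out)$alpha), 0.02)
})

test_that("alpha recovery holds across the operating range", {
  # compact per-trace version; the tighter mean-error bound over the full
  # repetition count lives in the acceptance suite
  for (a0 in c(-0.4, 0, 0.4)) {
    for (r in 1:10) {
      sk <- simulate_skewed_trace("random",
        alpha = a0, noise_sd = 0.01,
        seed = 600 + 50 * (a0 + 1) + r
      )
      m <- estimate_alpha(sk)
      expect_lt(abs(m$fit_slope_after), 1e-6)
      expect_lt(abs(m$alpha - a0), 0.3)
    }
  }
})

test_that("full reconstruction recovers a clean digit and is deterministic", {
  ep <- get_clean_epochs()[[1]] # digit 0
  tpl_poly <- normalize_box(eye_trace(builtin_templates()[[1]]$waypoints))$points
  expect_lt(oracle_polyline_distance(ep$trace$points, tpl_poly), 0.05)
  expect_true(ep$trace$normalized)
  expect_equal(nrow(ep$trace$points), 128L)

  again <- reconstruct(ep$recording)
  expect_identical(again$points, ep$trace$points)
})

test_that("recordings without saccadic content fail at the extract stage", {
  flat <- with_test_seed(10, matrix(rnorm(4 * 64 * 8, sd = 2), ncol = 4))
  colnames(flat) <- c("left", "right", "above", "below")
  rec <- eog_recording(flat, 64)
  expect_error(reconstruct(rec), "extract")
})

test_that("a clean two-stroke digit produces a two-segment trace with one corner", {
  tpls <- builtin_templates()
  cfg <- synth_config(
    noise_sd_uv = 0, drift_uv_per_s = 0,
    blink_rate_per_epoch = 0, alpha = 0
  )
  ep <- simulate_epoch(tpls[[2]], cfg, seed = 77) # digit 1
  out <- reconstruct(ep$recording, keep_stages = TRUE)
  expect_equal(out$trace$meta$n_segments, 2L)
  # away from the entry/exit hooks, sharp turning concentrates at a single
  # interior corner (adjacent sharp turns at the corner count once)
  p <- out$trace$points
  p <- p[4:(nrow(p) - 3), , drop = FALSE]
  d <- diff(p)
  ang <- atan2(d[, 2], d[, 1])
  turn <- abs(diff(ang))
  turn <- pmin(turn, 2 * pi - turn)
  sharp <- which(turn > 0.5)
  corners <- sum(diff(c(-10, sharp)) > 5)
  expect_equal(corners, 1L)
})

test_that("injected crosstalk is recovered in signal units through the pipeline", {
  tpls <- builtin_templates()
  cfg <- synth_config(
    noise_sd_uv = 0, drift_uv_per_s = 0,
    blink_rate_per_epoch = 0, alpha = 0.3
  )
  for (d in c(0, 5)) { # axis-aligned patterns, where alpha is identifiable
    ep <- simulate_epoch(tpls[[d + 1]], cfg, seed = 11 + d)
    tr <- reconstruct(ep$recording)
    expect_lt(abs(tr$meta$alpha_physical - 0.3), 0.05)
  }
})
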