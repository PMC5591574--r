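# Shared, lazily built fixtures. The full-size cohort is expensive, so it is
# simulated once per test run and cached for every file that needs it.

.fixture_cache <- new.env(parent = emptyenv())

# Full-size simulated cohort (18 participants x 3 trials x 10 digits) with
# reconstructed traces, mirroring the validation design of the study.
get_cohort_fixture <- function() {
  if (is.null(.fixture_cache$cohort)) {
    coh <- simulate_cohort(n_participants = 18, trials_per_digit = 3, seed = 1)
    traces <- lapply(coh$recordings, function(r) {
      tryCatch(reconstruct(r), error = function(e) NULL)
    })
    .fixture_cache$cohort <- list(cohort = coh, traces = traces)
  }
  .fixture_cache$cohort
}

# A clean (noise-, drift-, blink-free) epoch of each digit plus its
# reconstruction; used by fidelity and classification tests.
get_clean_epochs <- function() {
  if (is.null(.fixture_cache$clean)) {
    tpls <- builtin_templates()
    cfg <- synth_config(
      noise_sd_uv = 0, drift_uv_per_s = 0,
      blink_rate_per_epoch = 0, alpha = 0
    )
    eps <- lapply(0:9, function(d) {
      ep <- simulate_epoch(tpls[[d + 1]], cfg, seed = 100 + d)
      ep$trace <- reconstruct(ep$recording)
      ep
    })
    .fixture_cache$clean <- eps
  }
  .fixture_cache$clean
}

# A bare vertical-channel signal with raised-cosine blinks at given times.
synth_blink_signal <- function(rate = 64, dur_s = 6, blink_times = numeric(0),
                               amp = 300, blink_dur = 0.3, noise_sd = 0,
                               seed = 1) {
  with_test_seed(seed, {
    n <- round(dur_s * rate)
    v <- rnorm(n, sd = noise_sd)
    half <- round(blink_dur / 2 * rate)
    for (tc in blink_times) {
      c0 <- round(tc * rate)
      idx <- max(1, c0 - half):min(n, c0 + half)
      v[idx] <- v[idx] + amp * 0.5 * (1 + cos(pi * (idx - c0) / half))
    }
    v
  })
}
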