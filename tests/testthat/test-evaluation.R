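# Metrics, leave-one-subject-out validation, threshold sweep, visual angle.

diag_conf <- function(per_digit = 30L) {
  confusion_matrix(rep(0:9, each = per_digit), rep(0:9, each = per_digit))
}

test_that("overall accuracy is the diagonal fraction", {
  expect_equal(accuracy_overall(diag_conf()), 1)
  truth <- rep(0:9, each = 3)
  pred <- truth
  pred[c(1, 12, 25)] <- (truth[c(1, 12, 25)] + 1) %% 10
  expect_equal(accuracy_overall(confusion_matrix(truth, pred)), 27 / 30)
  # random matrix equals a direct loop
  with_test_seed(13, {
    t2 <- sample(0:9, 500, replace = TRUE)
    p2 <- sample(0:9, 500, replace = TRUE)
  })
  conf <- confusion_matrix(t2, p2)
  expect_equal(accuracy_overall(conf), sum(t2 == p2) / 500)
  expect_error(
    accuracy_overall(confusion_matrix(integer(0), integer(0))),
    "empty"
  )
})

test_that("per-digit precision, recall, and F1 follow their definitions", {
  # digit with 59 clean hits
  m <- diag_conf(59L)
  expect_equal(digit_metrics(m, 4), list(
    precision = 1, recall = 1, f1 = 1,
    defined = c(precision = TRUE, recall = TRUE, f1 = TRUE)
  ))
  # TP = 50, FP = 10, FN = 10
  truth <- c(rep(0, 60), rep(1, 10))
  pred <- c(rep(0, 50), rep(1, 10), rep(0, 10))
  dm <- digit_metrics(confusion_matrix(truth, pred), 0)
  expect_equal(dm$precision, 5 / 6)
  expect_equal(dm$recall, 5 / 6)
  expect_equal(dm$f1, 5 / 6)
  # published-style rounding: precision 98.00, recall 83.05 -> F1 89.91
  truth2 <- c(rep(4, 59), rep(3, 1))
  pred2 <- c(rep(4, 49), rep(0, 10), rep(4, 1))
  dm2 <- digit_metrics(confusion_matrix(truth2, pred2), 4)
  expect_equal(round(100 * dm2$precision, 2), 98.00)
  expect_equal(round(100 * dm2$recall, 2), 83.05)
  expect_equal(round(100 * dm2$f1, 2), 89.91)
  expect_equal(dm2$f1, 2 * dm2$precision * dm2$recall / (dm2$precision + dm2$recall))
})

test_that("undefined metrics report zero with a flag and F1 lies between P and R", {
  truth <- rep(0, 10)
  pred <- rep(1, 10) # digit 2 never appears
  dm <- digit_metrics(confusion_matrix(truth, pred), 2)
  expect_equal(dm$precision, 0)
  expect_false(dm$defined[["precision"]])
  with_test_seed(14, {
    t2 <- sample(0:9, 400, replace = TRUE)
    p2 <- sample(0:9, 400, replace = TRUE)
  })
  conf <- confusion_matrix(t2, p2)
  for (d in 0:9) {
    dm <- digit_metrics(conf, d)
    if (all(dm$defined)) {
      expect_gte(dm$f1, min(dm$precision, dm$recall))
      expect_lte(dm$f1, max(dm$precision, dm$recall))
    }
  }
})

make_trace_set <- function(n_participants, trials = 1L, noise = 0.03, seed = 70) {
  tpls <- builtin_templates()
  traces <- list()
  labels <- integer(0)
  parts <- character(0)
  for (s in seq_len(n_participants)) {
    for (tr in seq_len(trials)) {
      for (d in 0:9) {
        traces <- c(traces, list(simulate_skewed_trace(tpls[[d + 1]],
          alpha = 0.05 * s, noise_sd = noise,
          seed = seed + 1000 * s + 100 * tr + d
        )))
        labels <- c(labels, d)
        parts <- c(parts, sprintf("P%02d", s))
      }
    }
  }
  list(traces = traces, labels = labels, participants = parts)
}

test_that("LOSO evaluation is per-participant, deterministic, and exact on easy data", {
  s <- make_trace_set(3, trials = 2)
  rep <- loso_evaluate(s$traces, s$labels, s$participants, measure = "dpw", svm = FALSE)
  expect_equal(rep$overall_acc, 1) # near-noiseless variants are separable
  expect_length(rep$per_participant, 3L) # one fold per participant
  expect_equal(sum(rep$confusion), 60L)
  rep2 <- loso_evaluate(s$traces, s$labels, s$participants, measure = "dpw", svm = FALSE)
  expect_identical(rep2$predictions, rep$predictions)

  reps <- loso_evaluate(s$traces, s$labels, s$participants, measure = "dpw", svm = TRUE)
  expect_identical(
    reps$predictions,
    loso_evaluate(s$traces, s$labels, s$participants, measure = "dpw", svm = TRUE)$predictions
  )
  expect_error(
    loso_evaluate(s$traces[1:10], s$labels[1:10], rep("P1", 10)),
    ">= 2 participants"
  )
})

test_that("overall accuracy equals the attempt-weighted mean of participant accuracies", {
  s <- make_trace_set(4, trials = 1, noise = 0.12, seed = 90)
  rep <- loso_evaluate(s$traces, s$labels, s$participants, measure = "dtw", svm = FALSE)
  attempts <- table(s$participants)[names(rep$per_participant)]
  weighted <- sum(rep$per_participant * as.integer(attempts)) / sum(attempts)
  expect_equal(rep$overall_acc, weighted)
})

test_that("holdout participants are tested but never trained on", {
  s <- make_trace_set(3, trials = 2)
  rep <- loso_evaluate(s$traces, s$labels, s$participants,
    measure = "dpw", svm = FALSE, holdout = "P03"
  )
  expect_true("P03" %in% names(rep$per_participant))
  expect_equal(sum(rep$confusion), 60L)
})

test_that("evaluation reports round-trip through JSON", {
  s <- make_trace_set(2, trials = 1)
  rep <- loso_evaluate(s$traces, s$labels, s$participants, measure = "dtw", svm = FALSE)
  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep, f)
  back <- read_report(f)
  expect_equal(back$overall_acc, rep$overall_acc)
  expect_equal(back$per_participant, rep$per_participant)
  expect_equal(unclass(back$confusion), unclass(rep$confusion),
    ignore_attr = TRUE
  )
  expect_equal(back$per_digit$f1, rep$per_digit$f1)
  expect_equal(back$predictions, rep$predictions)
})

test_that("the threshold sweep reports accuracy per threshold and method", {
  tpls <- builtin_templates()
  cfg <- synth_config(blink_rate_per_epoch = 0) # keep the smoke test fast
  recs <- list()
  labels <- integer(0)
  parts <- character(0)
  for (s in 1:2) {
    for (d in 0:9) {
      ep <- simulate_epoch(tpls[[d + 1]], cfg, seed = 300 + 100 * s + d)
      recs <- c(recs, list(ep$recording))
      labels <- c(labels, d)
      parts <- c(parts, sprintf("P%d", s))
    }
  }
  out <- threshold_sweep(recs, labels, parts,
    thetas = c(120, 5e4),
    methods = c("dtw", "dpw")
  )
  expect_equal(nrow(out), 4L)
  expect_true(all(out$accuracy >= 0 & out$accuracy <= 1))
  # an absurdly high threshold destroys the traces and the accuracy
  lo <- out$accuracy[out$theta == 5e4]
  hi <- out$accuracy[out$theta == 120]
  expect_true(all(hi > lo))
  expect_true(all(lo <= 0.2))
  expect_error(threshold_sweep(recs, labels, parts, thetas = c(0, 120)), "> 0")
})

test_that("visual angle reproduces the closed form", {
  expect_equal(visual_angle(61, 62.5), 52.02, tolerance = 0.01 / 52.02)
  expect_equal(visual_angle(2, 1), 90)
  expect_lt(visual_angle(1e-6, 60), 1e-5)
  expect_error(visual_angle(0, 60), "positive")
  expect_error(visual_angle(61, -1), "positive")
})
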