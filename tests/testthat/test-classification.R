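# DTW/DPW dissimilarities, nearest-template decisions, normalization
# factors, and the SVM combination.

test_that("self-dissimilarity is zero and results are nonnegative", {
  for (seed in 1:5) {
    tr <- random_trace(12, seed)
    expect_equal(dtw_dissimilarity(tr, tr)$d, 0)
    expect_equal(dpw_dissimilarity(tr, tr)$d, 0)
    tr2 <- random_trace(9, seed + 100)
    expect_gte(dtw_dissimilarity(tr, tr2)$d, 0)
    expect_gte(dpw_dissimilarity(tr, tr2)$d, 0)
  }
})

test_that("the worked warp example matches the recursive oracle", {
  A <- eye_trace(cbind(c(0, 1, 2), c(0, 0, 0)))
  B <- eye_trace(cbind(c(0, 2), c(0, 0)))
  cons <- warp_constraints(2)
  expect_equal(dtw_dissimilarity(A, B, cons)$d, oracle_warp(A, B, 2, FALSE))
  expect_equal(dpw_dissimilarity(A, B, cons)$d, oracle_warp(A, B, 2, TRUE))
})

test_that("dynamic programs agree with the oracle on random small traces", {
  for (seed in 1:10) {
    nA <- 2 + seed %% 5
    nB <- 2 + (seed * 3) %% 5
    A <- random_trace(nA, seed)
    B <- random_trace(nB, seed + 50)
    for (M in 1:3) {
      cons <- warp_constraints(M)
      expect_equal(dtw_dissimilarity(A, B, cons)$d, oracle_warp(A, B, M, FALSE),
        tolerance = 1e-12
      )
      expect_equal(dpw_dissimilarity(A, B, cons)$d, oracle_warp(A, B, M, TRUE),
        tolerance = 1e-12
      )
    }
  }
})

test_that("DTW is symmetric under its symmetric step set", {
  for (seed in 1:50) {
    A <- random_trace(5 + seed %% 20, seed)
    B <- random_trace(5 + (seed * 7) %% 20, seed + 500)
    expect_equal(dtw_dissimilarity(A, B)$d, dtw_dissimilarity(B, A)$d,
      tolerance = 1e-12
    )
  }
})

test_that("the DP table is retained on request and ends at the reported value", {
  A <- random_trace(10, 1)
  B <- random_trace(8, 2)
  res <- dtw_dissimilarity(A, B, keep_table = TRUE)
  expect_equal(dim(res$table), c(10L, 8L))
  expect_equal(res$table[10, 8], res$d)
  expect_equal(res$table[1, 1], 0)
})

test_that("nearest-template classification recognizes templates and clean digits", {
  tpls <- builtin_templates()
  for (measure in c("dpw", "dtw")) {
    clf <- template_classifier(measure = measure)
    expect_equal(nearest_template(template_trace(tpls[[4]]), clf), 3)
  }
  eps <- get_clean_epochs()
  clf <- template_classifier(measure = "dpw")
  expect_equal(nearest_template(eps[[8]]$trace, clf), 7) # noiseless digit 7
})

test_that("normalization factors are class means and degenerate cases error", {
  tpls <- builtin_templates()
  clf <- template_classifier(measure = "dpw")
  train <- list()
  labels <- integer(0)
  for (d in 0:9) {
    for (r in 1:2) {
      train <- c(train, list(simulate_skewed_trace(tpls[[d + 1]],
        alpha = 0.1 * r,
        noise_sd = 0.02, seed = 40 + 10 * d + r
      )))
      labels <- c(labels, d)
    }
  }
  fitted <- fit_normalization(train, labels, clf)
  # hand-looped mean oracle
  for (d in c(0, 4, 9)) {
    idx <- which(labels == d)
    dd <- vapply(
      train[idx],
      function(tr) dpw_dissimilarity(tr, fitted$template_traces[[d + 1]])$d,
      numeric(1)
    )
    expect_equal(unname(fitted$factors[as.character(d)]), mean(dd))
  }
  expect_true(all(fitted$factors > 0))
  expect_error(fit_normalization(train[1:4], labels[1:4], clf), "lack classes")
  # exact template traces give zero factors: a degenerate training set
  exact <- lapply(tpls, template_trace)
  expect_error(fit_normalization(exact, 0:9, clf), "degenerate")
})

test_that("feature vectors are normalized dissimilarities", {
  tpls <- builtin_templates()
  clf <- template_classifier(measure = "dpw")
  expect_error(feature_vector(template_trace(tpls[[1]]), clf), "not fitted")
  clf$factors <- stats::setNames(rep(1, 10), as.character(0:9))
  fv <- feature_vector(template_trace(tpls[[6]]), clf)
  expect_equal(unname(fv["5"]), 0) # its own template at unit factor
  clf2 <- clf
  clf2$factors <- 2 * clf$factors
  expect_equal(feature_vector(template_trace(tpls[[6]]), clf2), fv / 2)
  # arg-min of the feature vector equals the nearest template at equal factors
  tr <- simulate_skewed_trace(tpls[[3]], alpha = 0.1, noise_sd = 0.03, seed = 3)
  expect_equal(as.integer(names(which.min(feature_vector(tr, clf)))), nearest_template(tr, clf))
})

test_that("the combined classifier trains, predicts, and is deterministic", {
  tpls <- builtin_templates()
  make_set <- function(offset) {
    train <- list()
    labels <- integer(0)
    for (d in 0:9) {
      for (r in 1:3) {
        train <- c(train, list(simulate_skewed_trace(tpls[[d + 1]],
          alpha = runif(1, -0.2, 0.2), noise_sd = 0.03,
          seed = offset + 10 * d + r
        )))
        labels <- c(labels, d)
      }
    }
    list(train = train, labels = labels)
  }
  s <- with_test_seed(55, make_set(7000))
  clf <- train_combined(s$train, s$labels, measure = "dpw")
  expect_s3_class(clf$svm, "svm")
  test_set <- with_test_seed(66, make_set(9000))
  preds <- predict(clf, test_set$train)
  expect_gte(mean(preds == test_set$labels), 0.9)
  expect_setequal(unique(preds), 0:9)

  # same data, second training run: identical predictions
  clf2 <- train_combined(s$train, s$labels, measure = "dpw")
  expect_identical(predict(clf2, test_set$train), preds)

  # without the SVM stage, predict() is exactly nearest_template
  clf0 <- train_combined(s$train, s$labels, measure = "dpw", svm = FALSE)
  for (tr in test_set$train[seq(1, 30, 3)]) {
    expect_equal(predict(clf0, tr), nearest_template(tr, clf0))
  }
})

test_that("value-axis warping separates skewed variants better than DTW", {
  # on skewed/scaled variants of the digit patterns, DPW's within-class
  # dissimilarity is a smaller fraction of its between-class dissimilarity
  # than DTW's: the motivation for warping on the value axis
  tpls <- builtin_templates()
  w_dpw <- c()
  w_dtw <- c()
  b_dpw <- c()
  b_dtw <- c()
  with_test_seed(99, {
    for (r in 1:200) {
      d <- (r - 1) %% 10
      base <- template_trace(tpls[[d + 1]])
      p <- base$points
      p[, 2] <- p[, 2] + runif(1, -0.3, 0.3) * p[, 1]
      p[, 1] <- p[, 1] * runif(1, 0.7, 1.3)
      p[, 2] <- p[, 2] * runif(1, 0.7, 1.3)
      p <- p + matrix(rnorm(length(p), sd = 0.02), ncol = 2)
      v <- eye_trace(p)
      other <- template_trace(tpls[[(d + 1 + sample(1:9, 1)) %% 10 + 1]])
      w_dpw <- c(w_dpw, dpw_dissimilarity(base, v)$d)
      w_dtw <- c(w_dtw, dtw_dissimilarity(base, v)$d)
      b_dpw <- c(b_dpw, dpw_dissimilarity(other, v)$d)
      b_dtw <- c(b_dtw, dtw_dissimilarity(other, v)$d)
    }
  })
  expect_lt(mean(w_dpw) / mean(b_dpw), mean(w_dtw) / mean(b_dtw))
})

test_that("warp constraints build the step set of the definition", {
  c3 <- warp_constraints(3)
  expect_equal(c3$M, 3L)
  expect_equal(nrow(c3$steps), 5L)
  expect_true(all(c3$steps[, 1] == 1L | c3$steps[, 2] == 1L))
  expect_error(warp_constraints(0), "positive")
  expect_error(dtw_dissimilarity(
    eye_trace(cbind(0:1, 0:1)),
    matrix(1, 1, 2)
  ), ">= 2 points")
})
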