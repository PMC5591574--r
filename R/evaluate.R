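# Evaluation: leave-one-subject-out validation, accuracy and per-digit
# precision/recall/F1, threshold sweeps, and the visual-angle helper.

#' Confusion matrix for digit predictions
#'
#' @param true,predicted Integer digit labels 0-9; `NA` predictions (e.g.
#'   failed reconstructions) are dropped from no cell but count as attempts
#'   in no column - they are tallied in the `failed` attribute.
#' @return A 10 x 10 integer matrix (rows = true, cols = predicted), class
#'   `confusion_matrix`, with attribute `failed` (count of NA predictions
#'   per true digit).
#' @export
confusion_matrix <- function(true, predicted) {
  true <- as.integer(true)
  predicted <- as.integer(predicted)
  if (length(true) != length(predicted)) stop_arg("length mismatch")
  if (any(!true %in% 0:9)) stop_arg("true labels must be digits 0-9")
  ok <- !is.na(predicted)
  m <- table(
    factor(true[ok], levels = 0:9),
    factor(predicted[ok], levels = 0:9)
  )
  m <- matrix(as.integer(m), 10L, 10L, dimnames = list(true = 0:9, predicted = 0:9))
  failed <- as.integer(table(factor(true[!ok], levels = 0:9)))
  structure(m, class = c("confusion_matrix", "matrix"), failed = failed)
}

#' Overall recognition accuracy
#'
#' The fraction of correctly classified patterns: the trace of the confusion
#' matrix divided by the total number of attempts (including failed ones).
#'
#' @param conf A [confusion_matrix()].
#' @return A fraction in \[0, 1\].
#' @export
accuracy_overall <- function(conf) {
  stopifnot(inherits(conf, "confusion_matrix"))
  failed <- attr(conf, "failed")
  total <- sum(conf) + sum(if (is.null(failed)) 0L else failed)
  if (total == 0L) stop_arg("empty confusion matrix")
  sum(diag(unclass(conf))) / total
}

#' Per-digit precision, recall and F1
#'
#' Precision = TP / (TP + FP), recall (sensitivity) = TP / (TP + FN), and F1
#' is their harmonic mean. A zero denominator makes the metric undefined; it
#' is reported as 0 with `defined = FALSE` so result tables stay rectangular.
#'
#' @param conf A [confusion_matrix()].
#' @param digit Digit label 0-9.
#' @return A list with `precision`, `recall`, `f1`, and `defined` (logical
#'   vector for the three metrics).
#' @export
digit_metrics <- function(conf, digit) {
  stopifnot(inherits(conf, "confusion_matrix"))
  digit <- as.integer(digit)
  if (!digit %in% 0:9) stop_arg("'digit' must be 0-9")
  m <- unclass(conf)
  k <- digit + 1L
  tp <- m[k, k]
  fp <- sum(m[, k]) - tp
  failed <- attr(conf, "failed")
  fn <- sum(m[k, ]) - tp + (if (is.null(failed)) 0L else failed[k])
  prec_def <- (tp + fp) > 0L
  rec_def <- (tp + fn) > 0L
  precision <- if (prec_def) tp / (tp + fp) else 0
  recall <- if (rec_def) tp / (tp + fn) else 0
  f1_def <- prec_def && rec_def && (precision + recall) > 0
  f1 <- if (f1_def) 2 * precision * recall / (precision + recall) else 0
  list(
    precision = precision, recall = recall, f1 = f1,
    defined = c(precision = prec_def, recall = rec_def, f1 = f1_def)
  )
}

#' Leave-one-subject-out evaluation
#'
#' For each participant, a classifier is trained on the traces of all other
#' (training-eligible) participants and tested on the held-out participant.
#' Templates stay fixed; only the normalization factors and the SVM are
#' refitted per fold. Dissimilarities to the 10 templates are computed once
#' and reused across folds.
#'
#' @param traces List of reconstructed [eye_trace()]s.
#' @param labels Integer digit labels, parallel to `traces`.
#' @param participants Participant ids, parallel to `traces` (>= 2 distinct).
#' @param measure `"dpw"` or `"dtw"`.
#' @param svm Combine with the SVM stage.
#' @param constraints A [warp_constraints()].
#' @param holdout Optional participant ids never used for training (they are
#'   still tested); use for groups whose data must not enter the models.
#' @param cost SVM regularization constant.
#' @param dist Increment distance.
#' @return An object of class `eval_report`: `overall_acc`,
#'   `per_participant` (named accuracies), `per_digit` (data frame with
#'   precision/recall/F1), `confusion`, `predictions`, and `config`.
#' @export
loso_evaluate <- function(traces, labels, participants,
                          measure = c("dpw", "dtw"), svm = TRUE,
                          constraints = warp_constraints(), holdout = NULL,
                          cost = 1, dist = "l1") {
  measure <- match.arg(measure)
  labels <- as.integer(labels)
  participants <- as.character(participants)
  stopifnot(length(traces) == length(labels), length(traces) == length(participants))
  ids <- unique(participants)
  if (length(ids) < 2L) stop_arg("leave-one-subject-out needs >= 2 participants")
  clf0 <- template_classifier(measure = measure, constraints = constraints, dist = dist)

  ok <- !vapply(traces, is.null, logical(1))
  D <- matrix(NA_real_, length(traces), 10L)
  D[ok, ] <- t(vapply(
    traces[ok], template_dissimilarities, numeric(10), clf = clf0
  ))

  train_pool <- setdiff(ids, as.character(holdout))
  preds <- rep(NA_integer_, length(traces))
  for (p in ids) {
    test_idx <- which(participants == p)
    tr_idx <- which(participants %in% setdiff(train_pool, p) & ok)
    if (!length(tr_idx)) stop_arg("no training data for fold '", p, "'")
    miss <- setdiff(0:9, unique(labels[tr_idx]))
    if (length(miss)) {
      stop_arg(
        "training fold for '", p, "' lacks classes: ",
        paste(miss, collapse = ", ")
      )
    }
    factors <- vapply(
      0:9,
      function(k) mean(D[tr_idx[labels[tr_idx] == k], k + 1L]),
      numeric(1)
    )
    if (any(factors <= 0)) stop_arg("degenerate normalization in fold '", p, "'")
    if (svm) {
      feats <- sweep(D[tr_idx, , drop = FALSE], 2L, factors, "/")
      colnames(feats) <- as.character(0:9)
      model <- e1071::svm(
        x = feats, y = factor(labels[tr_idx], levels = 0:9),
        kernel = "linear", cost = cost, scale = FALSE
      )
      tok <- test_idx[ok[test_idx]]
      if (length(tok)) {
        tf <- sweep(D[tok, , drop = FALSE], 2L, factors, "/")
        colnames(tf) <- as.character(0:9)
        preds[tok] <- as.integer(as.character(predict(model, tf)))
      }
    } else {
      tok <- test_idx[ok[test_idx]]
      if (length(tok)) {
        preds[tok] <- apply(D[tok, , drop = FALSE], 1L, which.min) - 1L
      }
    }
  }
  conf <- confusion_matrix(labels, preds)
  per_part <- vapply(ids, function(p) {
    i <- participants == p
    sum(!is.na(preds[i]) & preds[i] == labels[i]) / sum(i)
  }, numeric(1))
  per_digit <- do.call(rbind, lapply(0:9, function(d) {
    m <- digit_metrics(conf, d)
    data.frame(digit = d, precision = m$precision, recall = m$recall, f1 = m$f1)
  }))
  structure(
    list(
      overall_acc = accuracy_overall(conf),
      per_participant = stats::setNames(per_part, ids),
      per_digit = per_digit,
      confusion = conf,
      predictions = preds,
      config = list(
        measure = measure, svm = svm, M = constraints$M,
        dist = dist, cost = cost, holdout = as.character(holdout)
      )
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s%s: overall accuracy %.2f%% over %d participants\n",
    toupper(x$config$measure), if (x$config$svm) "+SVM" else "",
    100 * x$overall_acc, length(x$per_participant)
  ))
  cat("  per participant (%):", paste(
    sprintf("%s=%.1f", names(x$per_participant), 100 * x$per_participant),
    collapse = " "
  ), "\n")
  invisible(x)
}

#' Write / read an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `write_report`: invisibly, `path`. `read_report`: an
#'   `eval_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(
    overall_acc = report$overall_acc,
    per_participant = as.list(report$per_participant),
    per_digit = report$per_digit,
    confusion = unclass(report$confusion),
    failed = attr(report$confusion, "failed"),
    predictions = report$predictions,
    config = report$config
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::fromJSON(path)
  conf <- matrix(as.integer(raw$confusion), 10L, 10L,
    dimnames = list(true = 0:9, predicted = 0:9)
  )
  conf <- structure(conf,
    class = c("confusion_matrix", "matrix"),
    failed = as.integer(raw$failed)
  )
  structure(
    list(
      overall_acc = raw$overall_acc,
      per_participant = unlist(raw$per_participant),
      per_digit = raw$per_digit,
      confusion = conf,
      predictions = as.integer(raw$predictions),
      config = raw$config
    ),
    class = "eval_report"
  )
}

#' Accuracy as a function of the wavelet threshold
#'
#' Reconstructs every recording at each threshold and runs a
#' leave-one-subject-out evaluation per method, returning a plot-ready table.
#' Recordings that fail to reconstruct at a threshold (e.g. all coefficients
#' below it) count as failed attempts, not as successes.
#'
#' @param recordings List of [eog_recording()]s.
#' @param labels,participants Parallel digit labels and participant ids.
#' @param thetas Positive thresholds to sweep (0 is not admissible: it would
#'   mark every sample saccadic).
#' @param methods Character vector from `"dtw"`, `"dtw_svm"`, `"dpw"`,
#'   `"dpw_svm"`.
#' @param cfg Base [reconstruct_config()]; its `theta` is overridden.
#' @param constraints A [warp_constraints()].
#' @return Data frame with columns `theta`, `method`, `accuracy`.
#' @export
threshold_sweep <- function(recordings, labels, participants, thetas,
                            methods = c("dtw", "dtw_svm", "dpw", "dpw_svm"),
                            cfg = reconstruct_config(),
                            constraints = warp_constraints()) {
  if (any(thetas <= 0)) stop_arg("thresholds must be > 0")
  methods <- match.arg(methods, several.ok = TRUE)
  out <- data.frame()
  for (th in thetas) {
    cfg_th <- cfg
    cfg_th$theta <- th
    traces <- lapply(recordings, function(r) {
      tryCatch(reconstruct(r, cfg_th), error = function(e) NULL)
    })
    for (m in methods) {
      measure <- sub("_svm$", "", m)
      acc <- tryCatch(
        loso_evaluate(
          traces, labels, participants,
          measure = measure, svm = grepl("_svm$", m), constraints = constraints
        )$overall_acc,
        # a threshold so extreme that folds cannot even be trained scores 0
        error = function(e) 0
      )
      out <- rbind(out, data.frame(theta = th, method = m, accuracy = acc))
    }
  }
  out
}

#' Maximum visual angle subtended by a screen
#'
#' Full horizontal angle of a flat screen of the given width viewed from a
#' point at the given perpendicular distance from its center:
#' `2 * atan(width / 2 / distance)`, in degrees.
#'
#' @param width_cm Screen width (cm, > 0).
#' @param distance_cm Viewing distance (cm, > 0).
#' @return Angle in degrees.
#' @examples
#' visual_angle(61, 62.5) # 24-inch monitor at arm's length: ~52 degrees
#' @export
visual_angle <- function(width_cm, distance_cm) {
  if (any(width_cm <= 0) || any(distance_cm <= 0)) {
    stop_arg("width and distance must be positive")
  }
  2 * atan(width_cm / 2 / distance_cm) * 180 / pi
}
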