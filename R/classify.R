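# Classification of reconstructed traces against the digit templates:
# DTW and DPW dissimilarities (in derivative form, computed by a compiled
# dynamic program), nearest-template decisions, and the combination of
# normalized-dissimilarity feature vectors with a support vector machine.

#' Warping constraints for DTW/DPW
#'
#' The admissible warp steps are `{(1, m), (m, 1) | 1 <= m <= M}`: one
#' sequence advances a single sample while the other advances up to `M`.
#'
#' @param M Maximum warping step (>= 1). The default of 8 samples at 128
#'   trace points (about 6% of the sequence length) is a conventional slope
#'   constraint.
#' @return An object of class `warp_constraints`.
#' @export
warp_constraints <- function(M = 8L) {
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop_arg("'M' must be a positive integer")
  steps <- rbind(
    cbind(1L, seq_len(M)),
    if (M > 1L) cbind(seq.int(2L, M), 1L)
  )
  colnames(steps) <- c("C_A", "C_B")
  structure(list(M = M, steps = steps), class = "warp_constraints")
}

trace_points <- function(x) {
  if (inherits(x, "eye_trace")) x$points else as.matrix(x)
}

warp_dissimilarity <- function(A, B, constraints, positional, dist, keep_table) {
  pa <- trace_points(A)
  pb <- trace_points(B)
  if (nrow(pa) < 2L || nrow(pb) < 2L) stop_arg("both traces need >= 2 points")
  dist_type <- match.arg(dist, c("l1", "l2"))
  res <- warp_dp(
    pa, pb, constraints$M, positional,
    if (dist_type == "l1") 1L else 2L, keep_table
  )
  structure(
    list(
      d = res$d, table = res$table, L_A = res$L_A, L_B = res$L_B,
      measure = if (positional) "dpw" else "dtw"
    ),
    class = "dissimilarity_result"
  )
}

#' Dynamic time warping dissimilarity between two traces
#'
#' Derivative-form DTW: the cost of aligning position `i` of `A` with `j` of
#' `B` is the distance between the local increments `A(i) - A(i-1)` and
#' `B(j) - B(j-1)` (per-axis absolute differences summed, by default), plus
#' the cheapest admissible predecessor cell. The dissimilarity is the cost of
#' the final cell.
#'
#' @param A,B [eye_trace()] objects (or 2-column point matrices).
#' @param constraints A [warp_constraints()] object.
#' @param dist `"l1"` (default) or `"l2"` distance between 2-D increments.
#' @param keep_table Retain the full dynamic-programming cost table.
#' @return An object of class `dissimilarity_result` with elements `d`,
#'   `L_A`, `L_B`, and optionally `table`.
#' @export
dtw_dissimilarity <- function(A, B, constraints = warp_constraints(),
                              dist = "l1", keep_table = FALSE) {
  warp_dissimilarity(A, B, constraints, FALSE, dist, keep_table)
}

#' Dynamic positional warping dissimilarity between two traces
#'
#' DPW extends derivative-form DTW to 2-D shapes: the predecessor used for
#' the local increments is the one selected by the arg-min warp step, so
#' warping acts on the value axis as well as time. This makes the measure
#' more tolerant of locally stretched or skewed shapes.
#'
#' @inheritParams dtw_dissimilarity
#' @return An object of class `dissimilarity_result`.
#' @export
dpw_dissimilarity <- function(A, B, constraints = warp_constraints(),
                              dist = "l1", keep_table = FALSE) {
  warp_dissimilarity(A, B, constraints, TRUE, dist, keep_table)
}

#' @export
print.dissimilarity_result <- function(x, ...) {
  cat(sprintf(
    "<dissimilarity_result> %s d = %.4f (lengths %d, %d)\n",
    toupper(x$measure), x$d, x$L_A, x$L_B
  ))
  invisible(x)
}

#' Build a template classifier
#'
#' Bundles the 10 digit templates (as comparable traces), the dissimilarity
#' measure, and the warping constraints. Without fitted normalization factors
#' and SVM it classifies by the nearest template; [train_combined()] adds the
#' SVM stage.
#'
#' @param templates List of 10 [digit_template()]s (default: built-in set).
#' @param measure `"dpw"` (default) or `"dtw"`.
#' @param constraints A [warp_constraints()].
#' @param n_points Points per template trace; use the reconstruction value.
#' @param dist Increment distance, `"l1"` or `"l2"`.
#' @return An object of class `template_classifier`.
#' @export
template_classifier <- function(templates = builtin_templates(),
                                measure = c("dpw", "dtw"),
                                constraints = warp_constraints(),
                                n_points = 128L, dist = "l1") {
  measure <- match.arg(measure)
  labels <- vapply(templates, function(t) t$label, integer(1))
  if (!identical(sort(labels), 0:9)) {
    stop_arg("classifier needs exactly the 10 templates labeled 0-9")
  }
  templates <- templates[order(labels)]
  structure(
    list(
      template_traces = lapply(templates, template_trace, n_points = n_points),
      labels = 0:9, measure = measure, constraints = constraints,
      dist = dist, factors = NULL, svm = NULL
    ),
    class = "template_classifier"
  )
}

#' @export
print.template_classifier <- function(x, ...) {
  cat(sprintf(
    "<template_classifier> measure %s, M = %d%s%s\n",
    toupper(x$measure), x$constraints$M,
    if (!is.null(x$factors)) ", normalization fitted" else "",
    if (!is.null(x$svm)) ", SVM trained" else ""
  ))
  invisible(x)
}

# Dissimilarities from one trace to all 10 templates, ordered by label.
template_dissimilarities <- function(trace, clf) {
  fn <- if (clf$measure == "dpw") dpw_dissimilarity else dtw_dissimilarity
  vapply(
    clf$template_traces,
    function(tt) fn(trace, tt, clf$constraints, dist = clf$dist)$d,
    numeric(1)
  )
}

#' Nearest-template classification
#'
#' Assigns the label of the template with the minimal dissimilarity under
#' the classifier's measure. Ties break toward the lowest digit label.
#'
#' @param trace An [eye_trace()].
#' @param clf A [template_classifier()].
#' @return An integer digit label 0-9.
#' @export
nearest_template <- function(trace, clf) {
  stopifnot(inherits(clf, "template_classifier"))
  d <- template_dissimilarities(trace, clf)
  clf$labels[which.min(d)]
}

#' Fit per-class normalization factors
#'
#' For each class, the factor is the mean dissimilarity of the training
#' traces of that class to their own template. Dividing test dissimilarities
#' by these factors puts all 10 template distances on a comparable scale.
#'
#' @param traces List of training [eye_trace()]s.
#' @param labels Integer digit labels (0-9), parallel to `traces`.
#' @param clf A [template_classifier()].
#' @return The classifier with `factors` filled in (named numeric of 10).
#' @export
fit_normalization <- function(traces, labels, clf) {
  stopifnot(inherits(clf, "template_classifier"))
  labels <- as.integer(labels)
  if (length(traces) != length(labels)) stop_arg("'traces'/'labels' length mismatch")
  missing <- setdiff(0:9, unique(labels))
  if (length(missing)) {
    stop_arg("training data lack classes: ", paste(missing, collapse = ", "))
  }
  fn <- if (clf$measure == "dpw") dpw_dissimilarity else dtw_dissimilarity
  factors <- vapply(0:9, function(k) {
    idx <- which(labels == k)
    mean(vapply(
      traces[idx],
      function(tr) fn(tr, clf$template_traces[[k + 1L]], clf$constraints, dist = clf$dist)$d,
      numeric(1)
    ))
  }, numeric(1))
  if (any(factors <= 0)) {
    stop_arg(
      "degenerate normalization: zero mean dissimilarity for class ",
      paste(which(factors <= 0) - 1L, collapse = ", ")
    )
  }
  clf$factors <- stats::setNames(factors, as.character(0:9))
  clf
}

#' Normalized-dissimilarity feature vector
#'
#' Component `k` is the dissimilarity of the trace to template `k` divided by
#' the class-`k` normalization factor.
#'
#' @param trace An [eye_trace()].
#' @param clf A [template_classifier()] with fitted factors.
#' @return Numeric vector of length 10 (names "0".."9").
#' @export
feature_vector <- function(trace, clf) {
  stopifnot(inherits(clf, "template_classifier"))
  if (is.null(clf$factors)) {
    stop_arg("normalization factors not fitted; run fit_normalization() first")
  }
  stats::setNames(template_dissimilarities(trace, clf) / clf$factors, names(clf$factors))
}

#' Train a combined dissimilarity + SVM classifier
#'
#' Fits the per-class normalization factors, builds the 10-dimensional
#' normalized-dissimilarity feature vector for every training trace, and
#' trains a linear multi-class (one-vs-one) support vector machine on those
#' features.
#'
#' @param traces List of training [eye_trace()]s covering all 10 classes.
#' @param labels Integer digit labels, parallel to `traces`.
#' @param measure `"dpw"` or `"dtw"`.
#' @param constraints A [warp_constraints()].
#' @param svm Train the SVM stage (`TRUE`) or stop after normalization.
#' @param cost SVM regularization constant.
#' @param n_points,dist Passed to [template_classifier()].
#' @return A fitted [template_classifier()].
#' @export
train_combined <- function(traces, labels, measure = c("dpw", "dtw"),
                           constraints = warp_constraints(), svm = TRUE,
                           cost = 1, n_points = 128L, dist = "l1") {
  measure <- match.arg(measure)
  clf <- template_classifier(
    measure = measure, constraints = constraints,
    n_points = n_points, dist = dist
  )
  clf <- fit_normalization(traces, labels, clf)
  if (!svm) {
    return(clf)
  }
  feats <- t(vapply(traces, feature_vector, numeric(10), clf = clf))
  if (all(apply(feats, 2L, stats::sd) == 0)) {
    stop_arg("degenerate features: zero variance in every component")
  }
  clf$svm <- e1071::svm(
    x = feats, y = factor(labels, levels = 0:9),
    kernel = "linear", cost = cost, scale = FALSE
  )
  clf
}

#' Predict the digit of one or more traces
#'
#' With a trained SVM stage, the decision is the margin classifier applied to
#' the normalized-dissimilarity feature vector; otherwise the nearest
#' template wins.
#'
#' @param object A [template_classifier()].
#' @param newdata An [eye_trace()] or a list of them.
#' @param ... Unused.
#' @return Integer digit label(s).
#' @export
predict.template_classifier <- function(object, newdata, ...) {
  traces <- if (inherits(newdata, "eye_trace")) list(newdata) else newdata
  out <- vapply(traces, function(tr) {
    if (is.null(object$svm)) {
      return(nearest_template(tr, object))
    }
    fv <- matrix(feature_vector(tr, object), nrow = 1L)
    colnames(fv) <- names(object$factors)
    as.integer(as.character(predict(object$svm, fv)))
  }, integer(1))
  if (inherits(newdata, "eye_trace")) out[[1L]] else out
}
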