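# Canonical digit patterns: simplified, corner-to-corner polylines on a
# 3 x 3 writing lattice, designed so a digit can be written with a short
# sequence of saccades while keeping the recognizable shape of the numeral.
# The set ships as a reviewable JSON data file; templates contain no
# fixation parts, matching how traces are extracted.

#' Built-in digit templates
#'
#' Loads the canonical eye-writing patterns for the digits 0-9. Each is a
#' polyline on the integer lattice (columns and rows 0..2, origin
#' bottom-left, y up); writing starts at the first waypoint. The pattern for
#' '1' is placed on the central column of the canvas.
#'
#' @param path Path to a template JSON file (a list of
#'   `{label, waypoints: [[col,row], ...]}` records). Defaults to the file
#'   shipped with the package.
#' @return A list of 10 [digit_template()] objects, ordered by label.
#' @examples
#' tpls <- builtin_templates()
#' tpls[[1]]
#' @export
builtin_templates <- function(path = system.file("extdata", "templates.json",
                                package = "eyescript"
                              )) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tpls <- lapply(raw, function(rec) {
    wp <- do.call(rbind, lapply(rec$waypoints, unlist))
    digit_template(rec$label, wp)
  })
  labels <- vapply(tpls, function(t) t$label, integer(1))
  tpls <- tpls[order(labels)]
  if (!identical(sort(labels), 0:9)) {
    stop_arg("template set must contain exactly the labels 0-9")
  }
  tpls
}

#' Convert a digit template to a comparable trace
#'
#' Builds the polyline through the template waypoints, resamples it to
#' equidistant points and normalizes it to the unit box, producing an
#' [eye_trace()] directly comparable with reconstructed traces.
#'
#' @param tpl A [digit_template()].
#' @param n_points Number of points (>= 2); use the same value as for
#'   reconstruction.
#' @return A normalized [eye_trace()].
#' @export
template_trace <- function(tpl, n_points = 128L) {
  stopifnot(inherits(tpl, "digit_template"))
  tr <- eye_trace(tpl$waypoints, meta = list(label = tpl$label))
  normalize_box(resample_equidistant(tr, n_points))
}
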