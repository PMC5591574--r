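# Reading and writing recordings, bipolar exports, and dataset manifests.
#
# The native on-disk format is deliberately plain: a comma-separated file
# whose first line carries the sampling rate ("rate=<Hz>") followed by a
# standard CSV header and numeric payload. Files are self-describing and
# diff-friendly. EDF/BDF-family readers can be plugged in through
# register_recording_reader() without making the core depend on them.

.reader_registry <- new.env(parent = emptyenv())

#' Register a reader for an additional recording file format
#'
#' The built-in reader handles the package's CSV dialect. Formats such as
#' EDF/BDF can be supported by registering a function that takes a file path
#' and a channel layout and returns an [eog_recording()].
#'
#' @param extension File extension without the dot (e.g. `"edf"`),
#'   case-insensitive.
#' @param reader Function of `(path, layout)` returning an [eog_recording()].
#' @return Invisibly, the previous reader for that extension (or `NULL`).
#' @export
register_recording_reader <- function(extension, reader) {
  stopifnot(is.character(extension), length(extension) == 1L, is.function(reader))
  ext <- tolower(extension)
  old <- .reader_registry[[ext]]
  .reader_registry[[ext]] <- reader
  invisible(old)
}

file_ext <- function(path) tolower(sub(".*\\.", "", basename(path)))

parse_rate_header <- function(line, path) {
  m <- regmatches(line, regexec("^rate=([0-9.eE+-]+)$", trimws(line)))[[1]]
  if (length(m) != 2L) {
    stop_arg("'", path, "' is not a recording CSV: first line must be 'rate=<Hz>'")
  }
  rate <- suppressWarnings(as.numeric(m[2]))
  if (is.na(rate) || rate <= 0) stop_arg("invalid sampling rate in header of '", path, "'")
  rate
}

#' Read a raw EOG recording
#'
#' Reads the package's CSV recording format (first line `rate=<Hz>`, then a
#' header line of channel names, then one numeric column per channel) or any
#' format registered via [register_recording_reader()].
#'
#' @param path Path to the recording file.
#' @param layout Channel-role layout: a named character vector mapping the
#'   roles `left`, `right`, `above`, `below` to column names, or a named
#'   integer vector mapping them to column positions. The default expects
#'   columns named after the roles.
#' @return An [eog_recording()].
#' @examples
#' rec <- eog_recording(matrix(rnorm(400), ncol = 4), rate = 64)
#' f <- tempfile(fileext = ".csv")
#' write_recording(rec, f)
#' rec2 <- read_recording(f)
#' all.equal(rec$samples, rec2$samples)
#' @export
read_recording <- function(path,
                           layout = c(
                             left = "left", right = "right",
                             above = "above", below = "below"
                           )) {
  if (!file.exists(path)) stop_arg("file not found: '", path, "'")
  ext <- file_ext(path)
  if (ext != "csv") {
    reader <- .reader_registry[[ext]]
    if (is.null(reader)) {
      stop_arg(
        "no reader registered for '.", ext, "' files; ",
        "use register_recording_reader() to add one"
      )
    }
    return(reader(path, layout))
  }
  first <- readLines(path, n = 1L)
  rate <- parse_rate_header(first, path)
  df <- read.csv(path, skip = 1L, header = TRUE, check.names = FALSE)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop_arg("non-numeric payload in '", path, "'")
  }
  roles <- c("left", "right", "above", "below")
  if (!all(roles %in% names(layout))) {
    stop_arg("layout must name all roles: ", paste(roles, collapse = ", "))
  }
  if (is.character(layout)) {
    missing_cols <- setdiff(unname(layout[roles]), names(df))
    if (length(missing_cols)) {
      stop_arg(
        "recording '", path, "' lacks columns for roles: ",
        paste(names(layout)[layout %in% missing_cols], collapse = ", ")
      )
    }
    idx <- match(unname(layout[roles]), names(df))
  } else {
    idx <- as.integer(layout[roles])
    if (anyNA(idx) || any(idx < 1L) || any(idx > ncol(df))) {
      stop_arg("layout column indices out of range for '", path, "'")
    }
  }
  eog_recording(
    as.matrix(df), rate,
    channels = stats::setNames(idx, roles),
    meta = list(path = path)
  )
}

#' Write a raw EOG recording
#'
#' Writes the CSV dialect read by [read_recording()]. Values are stored with
#' 15 significant digits, so a write/read round trip reproduces the samples
#' to double precision.
#'
#' @param rec An [eog_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eog_recording"))
  cols <- colnames(rec$samples)
  if (is.null(cols)) {
    cols <- rep("", ncol(rec$samples))
  }
  # ensure role columns carry their role name so the default layout re-reads
  cols[rec$channels] <- names(rec$channels)
  blank <- !nzchar(cols)
  cols[blank] <- paste0("ch", which(blank))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_arg("cannot write '", path, "': ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(sprintf("rate=%.10g", rec$rate), con)
  writeLines(paste(cols, collapse = ","), con)
  m <- format(rec$samples, digits = 15, trim = TRUE, scientific = TRUE)
  writeLines(apply(m, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Write a bipolar signal pair as CSV
#'
#' Two-column (`h`, `v`) export with the same `rate=` header convention as
#' [write_recording()].
#'
#' @param sig A [bipolar_signal()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bipolar <- function(sig, path) {
  stopifnot(inherits(sig, "bipolar_signal"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_arg("cannot write '", path, "': ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(sprintf("rate=%.10g", sig$rate), con)
  writeLines("h,v", con)
  writeLines(
    paste(
      format(sig$h, digits = 15, trim = TRUE, scientific = TRUE),
      format(sig$v, digits = 15, trim = TRUE, scientific = TRUE),
      sep = ","
    ),
    con
  )
  invisible(path)
}

#' Read a bipolar signal pair from CSV
#'
#' @param path Path written by [write_bipolar()].
#' @return A [bipolar_signal()].
#' @export
read_bipolar <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: '", path, "'")
  rate <- parse_rate_header(readLines(path, n = 1L), path)
  df <- read.csv(path, skip = 1L, header = TRUE)
  if (!all(c("h", "v") %in% names(df))) stop_arg("'", path, "' lacks h/v columns")
  bipolar_signal(df$h, df$v, rate)
}

#' Load a manifest-indexed dataset of recordings
#'
#' A manifest is a CSV with columns `participant`, `trial`, `digit`, `path`
#' (paths relative to `root` unless absolute). Groups by participant are the
#' unit of leave-one-subject-out evaluation.
#'
#' @param root Directory against which relative manifest paths are resolved.
#' @param manifest Path to the manifest CSV.
#' @param layout Channel layout passed to [read_recording()].
#' @return A list with `index` (data frame: participant, trial, digit, path)
#'   and `recordings` (list of [eog_recording()] in manifest order).
#' @export
load_dataset <- function(root, manifest,
                         layout = c(
                           left = "left", right = "right",
                           above = "above", below = "below"
                         )) {
  if (!file.exists(manifest)) stop_arg("manifest not found: '", manifest, "'")
  idx <- read.csv(manifest, header = TRUE, stringsAsFactors = FALSE)
  need <- c("participant", "trial", "digit", "path")
  if (!all(need %in% names(idx))) {
    stop_arg("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(idx) == 0L) {
    return(list(index = idx[, need], recordings = list()))
  }
  if (any(!idx$digit %in% 0:9)) stop_arg("manifest digit labels must be in 0..9")
  if (any(!nzchar(as.character(idx$participant)))) {
    stop_arg("manifest participant ids must be non-empty")
  }
  paths <- ifelse(
    grepl("^(/|[A-Za-z]:)", idx$path), idx$path, file.path(root, idx$path)
  )
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop_arg(
      "manifest references missing files: ",
      paste(utils::head(paths[missing], 5L), collapse = ", "),
      if (sum(missing) > 5L) sprintf(" (and %d more)", sum(missing) - 5L) else ""
    )
  }
  recs <- lapply(paths, read_recording, layout = layout)
  for (i in seq_along(recs)) {
    recs[[i]]$meta$participant <- idx$participant[i]
    recs[[i]]$meta$trial <- idx$trial[i]
    recs[[i]]$meta$digit <- idx$digit[i]
  }
  list(index = idx[, need], recordings = recs)
}
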