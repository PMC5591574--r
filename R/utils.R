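# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded simulation
#' helpers never disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed and stream indices, staying well
# inside 32-bit integer range.
child_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483629
  for (k in idx) {
    x <- (x * 48271 + as.double(k) * 9973 + 1) %% 2147483629
  }
  as.integer(x)
}

stop_arg <- function(...) stop(..., call. = FALSE)

# Odd sample count nearest to a duration in ms (>= 1).
odd_window <- function(ms, rate) {
  w <- max(1L, round(ms / 1000 * rate))
  if (w %% 2L == 0L) w <- w + 1L
  as.integer(w)
}

# Maximal runs of TRUE in a logical vector, as a 2-column matrix (start, end).
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Indices of strict local maxima/minima of a series (plateaus take the first
# sample of the plateau).
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) {
    return(list(max = integer(0), min = integer(0)))
  }
  d <- diff(x)
  s <- sign(d)
  # carry sign through flat stretches so plateaus register once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  turn <- diff(s)
  list(
    max = which(turn < 0) + 1L,
    min = which(turn > 0) + 1L
  )
}
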