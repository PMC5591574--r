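# Independent reference implementations used to validate the package's
# optimized code paths. These are deliberately written as direct, slow
# translations of the defining equations (plain recursion and loops), with
# no shared code with the implementations they check.

# Dissimilarity between 2-D traces by direct recursive evaluation of the
# dynamic-programming equations, without memoization. Warp steps are
# {(1, m), (m, 1) | 1 <= m <= M}; predecessor indices clamp at 1 and
# tau(1, 1) = 0. In time-warping mode the local increments are always
# one-sample; in positional mode they follow the warp step, and the
# minimization is joint over increment cost plus predecessor cost.
oracle_warp <- function(A, B, M, positional = FALSE, dist = "l1") {
  A <- unclass(A)
  if (is.list(A)) A <- A$points
  B <- unclass(B)
  if (is.list(B)) B <- B$points
  steps <- rbind(cbind(1, seq_len(M)), if (M > 1) cbind(seq.int(2, M), 1))
  cost <- function(da, db) {
    if (dist == "l1") sum(abs(da - db)) else sqrt(sum((da - db)^2))
  }
  tau <- function(i, j) {
    if (i == 1 && j == 1) {
      return(0)
    }
    vals <- numeric(nrow(steps))
    for (c in seq_len(nrow(steps))) {
      pi <- max(i - steps[c, 1], 1)
      pj <- max(j - steps[c, 2], 1)
      if (positional) {
        da <- A[i, ] - A[pi, ]
        db <- B[j, ] - B[pj, ]
        vals[c] <- cost(da, db) + tau(pi, pj)
      } else {
        vals[c] <- tau(pi, pj)
      }
    }
    if (positional) {
      min(vals)
    } else {
      da <- A[i, ] - A[max(i - 1, 1), ]
      db <- B[j, ] - B[max(j - 1, 1), ]
      cost(da, db) + min(vals)
    }
  }
  tau(nrow(A), nrow(B))
}

# Haar wavelet coefficients by an explicit double loop over the discretized
# inner product, with reflection padding.
oracle_haar <- function(signal, scale) {
  n <- length(signal)
  h <- scale %/% 2
  pad <- c(rev(signal[1:h]), signal, rev(signal[(n - h + 1):n]))
  out <- numeric(n)
  for (b in 1:n) {
    pos <- b + h # position of b in padded coordinates
    acc <- 0
    for (k in 1:h) acc <- acc + pad[pos + k] # half-window after b
    for (k in 1:h) acc <- acc - pad[pos - k + 1] # half-window before b
    out[b] <- acc / sqrt(scale)
  }
  out
}

# Sliding median by explicit sort per window, reflection padding.
oracle_sliding_median <- function(x, window) {
  n <- length(x)
  h <- (window - 1) %/% 2
  pad <- c(rev(x[1:h]), x, rev(x[(n - h + 1):n]))
  out <- numeric(n)
  for (i in 1:n) {
    out[i] <- sort(pad[i:(i + 2 * h)])[h + 1]
  }
  out
}

# Mean distance from a set of points to the nearest point of a polyline.
oracle_polyline_distance <- function(points, poly) {
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- max(0, min(1, t))
    sqrt(sum((p - (a + t * ab))^2))
  }
  mean(apply(points, 1, function(p) {
    min(vapply(
      seq_len(nrow(poly) - 1),
      function(i) seg_dist(p, poly[i, ], poly[i + 1, ]),
      numeric(1)
    ))
  }))
}

# Random trace of n points with coordinates in [0, 1].
random_trace <- function(n, seed) {
  with_test_seed(seed, eye_trace(matrix(runif(2 * n), ncol = 2)))
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
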