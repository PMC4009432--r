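#' Binary hypercube geometry
#'
#' Memory items and addresses both live in \{0,1\}^n.  A bit vector is
#' represented as a plain integer vector of 0s and 1s; helper functions
#' below validate, generate and compare them.
#'
#' @name bitspace
NULL

# Validate a bit vector; returns it as integer.
check_bitvector <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) < 1) {
    stop(sprintf("'%s' must be a non-empty numeric vector of 0s and 1s", arg))
  }
  if (anyNA(x) || any(x != 0 & x != 1)) {
    stop(sprintf("'%s' contains values other than 0 and 1", arg))
  }
  as.integer(x)
}

#' Hamming distance between two bit vectors
#'
#' The number of positions in which the bits differ.  Vectors of unequal
#' dimension are incomparable and raise an error rather than returning
#' `FALSE` or recycling.
#'
#' @param a,b bit vectors (0/1 integer vectors) of equal length.
#' @return A non-negative integer in `[0, n]`.
#' @examples
#' hamming_distance(c(0, 0, 1, 1, 0), c(0, 1, 1, 0, 0)) # 2
#' @export
hamming_distance <- function(a, b) {
  a <- check_bitvector(a, "a")
  b <- check_bitvector(b, "b")
  if (length(a) != length(b)) {
    stop("dimension mismatch: vectors of length ", length(a), " and ",
      length(b), " are incomparable")
  }
  sum(a != b)
}

#' Generate a uniform random bit vector
#'
#' Each bit is i.i.d. Bernoulli(1/2), so the Hamming distance between two
#' random vectors is Binomial(n, 1/2) with mean n/2 and sd sqrt(n/4).
#'
#' @param n positive integer dimension.
#' @param seed optional integer seed; when given, the global RNG state is
#'   left untouched and the same seed always yields the same vector.
#' @return An integer vector of `n` 0/1 values.
#' @export
random_bitvector <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop("'n' must be a positive integer")
  }
  n <- as.integer(n)
  with_seed(seed, as.integer(stats::rbinom(n, 1L, 0.5)))
}

#' Generate a cue at an exact Hamming distance from a target
#'
#' Flips exactly `x` positions of `target`, chosen uniformly without
#' replacement.  Used to probe the memory at controlled cue quality.
#'
#' @param target bit vector.
#' @param x integer distance, `0 <= x <= length(target)`.
#' @param seed optional integer seed for the flipped-position draw.
#' @return A bit vector with `hamming_distance(result, target) == x`.
#' @export
make_cue_at_distance <- function(target, x, seed = NULL) {
  target <- check_bitvector(target, "target")
  n <- length(target)
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > n) {
    stop("'x' must be an integer in [0, ", n, "]")
  }
  x <- as.integer(x)
  if (x == 0L) return(target)
  flip <- with_seed(seed, sample.int(n, x))
  target[flip] <- 1L - target[flip]
  target
}

#' Distance-distribution statistics of the hypercube
#'
#' The distance from a fixed point to a uniform random point is
#' Binomial(n, 1/2): mean n/2 and standard deviation sqrt(n/4).  Almost
#' all of the space therefore lies within a few sd of n/2 from any point.
#'
#' @param n positive integer dimension.
#' @return A list with components `mean` (= n/2) and `sd` (= sqrt(n/4)).
#' @examples
#' distance_stats(1000) # mean 500, sd 15.81
#' @export
distance_stats <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop("'n' must be a positive integer")
  }
  list(mean = n / 2, sd = sqrt(n / 4))
}

#' Probability that a random point falls within an activation radius
#'
#' Exact binomial tail `P(d <= r)` for the Hamming distance `d` between a
#' fixed center and a uniform random point: `2^-n * sum_{k<=r} C(n, k)`.
#' Computed in log space, so it does not underflow even for n of several
#' thousand; request `log = TRUE` for radii deep in the tail.
#'
#' @param n dimension.
#' @param r integer radius, `0 <= r <= n`.
#' @param log return the log probability.
#' @return The activation probability (or its log).
#' @examples
#' activation_probability(1000, 451) # ~0.00107
#' @export
activation_probability <- function(n, r, log = FALSE) {
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r > n) {
    stop("'r' must be an integer in [0, ", n, "]")
  }
  lp <- stats::pbinom(r, n, 0.5, log.p = TRUE)
  if (log) lp else exp(lp)
}

#' Select the access radius for a target activation fraction
#'
#' Returns the integer radius whose exact binomial activation probability
#' is closest to `target_fraction`, ties broken toward the smaller
#' radius.  With the conventional fraction of 1/1000 this gives r = 451
#' for n = 1000 and r = 103 for n = 256 (roughly n/2 - 3*sqrt(n/4)).
#'
#' @param n dimension.
#' @param target_fraction desired mean fraction of hard locations
#'   activated per operation, in (0, 1].
#' @return An integer radius in `[0, n]`.
#' @examples
#' select_access_radius(1000, 0.001) # 451
#' select_access_radius(256, 0.001)  # 103
#' @export
select_access_radius <- function(n, target_fraction) {
  if (!is.numeric(target_fraction) || length(target_fraction) != 1 ||
      is.na(target_fraction) || target_fraction <= 0 || target_fraction > 1) {
    stop("'target_fraction' must be in (0, 1]")
  }
  # compare in whichever tail is computed without cancellation, so that
  # e.g. fraction 1 selects r = n rather than the first radius whose
  # lower tail rounds to 1 in floating point
  dev <- if (target_fraction > 0.5) {
    abs(stats::pbinom(0:n, n, 0.5, lower.tail = FALSE) -
      (1 - target_fraction))
  } else {
    abs(stats::pbinom(0:n, n, 0.5) - target_fraction)
  }
  # which.min takes the first (smallest radius) on ties
  as.integer(which.min(dev) - 1L)
}

#' Read bit vectors from a plain-text file
#'
#' One vector per line, characters '0'/'1' with no separators; bit 1 of
#' the vector is the first character of the line.  All lines must have
#' the same length.
#'
#' @param path file path.
#' @return An integer matrix, one row per vector.
#' @export
read_bitvectors <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no bit vectors in '", path, "'")
  n <- nchar(lines[1])
  for (i in seq_along(lines)) {
    if (nchar(lines[i]) != n) {
      stop("line ", i, ": length ", nchar(lines[i]),
        " differs from line 1 (", n, ")")
    }
    if (grepl("[^01]", lines[i])) {
      stop("line ", i, ": characters other than '0'/'1'")
    }
  }
  mat <- matrix(0L, length(lines), n)
  for (i in seq_along(lines)) {
    mat[i, ] <- as.integer(strsplit(lines[i], "", fixed = TRUE)[[1]])
  }
  mat
}

#' Write bit vectors to a plain-text file
#'
#' @param x a bit vector or a matrix with one vector per row.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bitvectors <- function(x, path) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  lines <- apply(x, 1, function(row) {
    paste(check_bitvector(row, "x"), collapse = "")
  })
  writeLines(lines, path)
  invisible(path)
}
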