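#' Critical-distance theory
#'
#' Analytic machinery for the convergence/divergence boundary of
#' iterated reading.  For a cue at Hamming distance d from a stored
#' target, the activated assembly contains a signal of w*phi(d) target
#' copies (w rehearsals, phi(d) shared locations) against theta(d)
#' random stored bits.  The per-bit wrong-read probability follows from
#' a Binomial(theta, 1/2) counter sum, and the critical distance is the
#' integer d minimizing f~(d) = (P(wrong) - d/n)^2, i.e. the fixed point
#' of "expected read-output distance equals cue distance".
#'
#' @name critical-distance-theory
NULL

# log P(a uniform random point is within r of BOTH of two centers d
# apart).  Among the d disagreeing coordinates the point differs from
# center A in k; among the n-d agreeing ones in j.  Then
# dist(A) = k + j and dist(B) = (d-k) + j, so
# P = 2^-n sum_k C(d,k) sum_{j <= jmax(k)} C(n-d, j),
# with the inner sum taken as an exact binomial tail in log space.
log_p_both <- function(n, r, d) {
  if (d < 0 || d > n) stop("'d' must be in [0, ", n, "]")
  if (r < 0 || r > n) stop("'r' must be in [0, ", n, "]")
  k <- 0:d
  jmax <- pmin(n - d, r - k, r - (d - k))
  ok <- jmax >= 0
  if (!any(ok)) return(-Inf)
  terms <- lchoose(d, k[ok]) - d * log(2) +
    stats::pbinom(jmax[ok], n - d, 0.5, log.p = TRUE)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

#' Expected number of hard locations shared by two activation circles
#'
#' The mean number of the `H` uniformly sampled hard locations lying
#' within radius `r` of both of two centers `d` bits apart:
#' `H * 2^-n * sum_{k,j} C(d,k) C(n-d,j)` over pairs with
#' `k+j <= r` and `(d-k)+j <= r`.  Evaluated in log space (exact
#' binomial tails), so it is accurate for n in the thousands.
#'
#' At `d = 0` this is `H * activation_probability(n, r)`; it is
#' non-increasing in `d` and exactly zero for `d > 2r` (disjoint balls).
#'
#' @param n dimension.
#' @param r inclusive access radius.
#' @param H number of hard locations.
#' @param d center distance in bits (vectorized).
#' @return Expected shared-location count(s).
#' @seealso [shared_assembly_count()] for the overlap normalized to a
#'   nominal assembly size, which reproduces Kanerva's published tables.
#' @export
shared_circle_count <- function(n, r, H, d) {
  vapply(d, function(di) H * exp(log_p_both(n, r, di)), numeric(1))
}

#' Circle overlap normalized to a nominal assembly size
#'
#' `h * P(within r of both) / P(within r of one)`: the expected number
#' of shared locations between two cell assemblies when a single
#' assembly is taken to contain `h` locations.  Kanerva's classical
#' overlap tables for the 1000-dimensional memory are stated for
#' assemblies of exactly 1000 locations and match this normalization
#' (97 shared at d = 200, 87 at d = 209 for r = 451), whereas the raw
#' count [shared_circle_count()] uses the unconditional expected
#' assembly size `H * activation_probability(n, r)` (~1072 for the same
#' geometry).  The two coincide when `h` equals that expectation.
#'
#' @param n dimension.
#' @param r inclusive access radius.
#' @param h nominal number of locations activated per operation.
#' @param d center distance in bits (vectorized).
#' @return Expected shared-location count(s) on the `h` scale.
#' @examples
#' round(shared_assembly_count(1000, 451, 1000, c(200, 209))) # 97 87
#' @export
shared_assembly_count <- function(n, r, h, d) {
  lp1 <- stats::pbinom(r, n, 0.5, log.p = TRUE)
  vapply(d, function(di) h * exp(log_p_both(n, r, di) - lp1), numeric(1))
}

#' Parameter set for the critical-distance theory
#'
#' @param n dimension.
#' @param H total number of hard locations.
#' @param r access radius.
#' @param s total number of stored bitstrings (including the target's
#'   own writes).
#' @param w number of times the target was written (rehearsal count).
#' @param h nominal number of locations activated per operation; default
#'   is the analytic expectation `H * activation_probability(n, r)`.
#'   The classical 1000-dimensional worked example sets `h = 1000`.
#' @return An object of class `theory_params`.
#' @examples
#' theory_params(1000, 1e6, 451, s = 1e4, w = 1, h = 1000)
#' @export
theory_params <- function(n, H, r, s, w = 1, h = NULL) {
  stopifnot(n >= 1, H >= 1, r >= 0, r <= n, s > 0, w >= 0)
  p1 <- activation_probability(n, r)
  if (is.null(h)) h <- H * p1
  stopifnot(h > 0, h <= H)
  expected <- H * p1
  if (abs(h - expected) / expected > 0.2) {
    warning(sprintf(
      "h = %g is inconsistent with H * activation_probability = %.1f (>20%%)",
      h, expected))
  }
  structure(list(n = as.integer(n), H = H, r = as.integer(r), s = s,
    w = w, h = h), class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat(sprintf(
    "Theory parameters: n = %d, H = %g, r = %d, h = %g, s = %g, w = %g\n",
    x$n, x$H, x$r, x$h, x$s, x$w))
  cat(sprintf("  load s*h^2/H = %g random bits per read\n",
    x$s * x$h^2 / x$H))
  invisible(x)
}

# phi(d) used by the theory layer: assembly-normalized overlap on the
# nominal h scale (reproduces the published worked example when
# h = 1000); callers may override with table values.
theory_phi <- function(params, d, phi = NULL) {
  if (!is.null(phi)) return(phi)
  shared_assembly_count(params$n, params$r, params$h, d)
}

#' Cell-assembly noise load theta(d)
#'
#' Expected number of random (non-target) stored bitstrings across the
#' activated assembly of a cue at distance d from the target:
#' `theta = s*h^2/H - w*phi(d)`.  The shared locations hold the target
#' `w` times, which displaces that many random items from the count.
#'
#' @param params a [theory_params()] object.
#' @param d cue distance in bits.
#' @param phi optional override for phi(d) (e.g. a published table
#'   value); default is the analytic [shared_assembly_count()].
#' @return theta(d); an error if the parameters put it below zero
#'   (over-rehearsed regime outside the model's validity).
#' @examples
#' cp <- theory_params(1000, 1e6, 451, s = 1e4, w = 1, h = 1000)
#' theta(cp, 200, phi = 97) # 9903
#' @export
theta <- function(params, d, phi = NULL) {
  stopifnot(inherits(params, "theory_params"))
  phi <- theory_phi(params, d, phi)
  th <- params$s * params$h^2 / params$H - params$w * phi
  if (any(th < 0)) {
    stop("theta < 0: rehearsal count w too large for this load ",
      "(model not valid in this regime)")
  }
  th
}

#' Per-bit probability of reading the wrong bit value
#'
#' The counter sum over the assembly is `w*phi(d)` target votes plus a
#' Binomial(theta, 1/2) random-bit sum.  With `T = s*h^2/(2H)` (half the
#' stored bits per assembly):
#' `P(wrong) = 1/2 * [(1 - alpha) + beta]`, where
#' `alpha = P(X < T)` and `beta = P(X < T - w*phi(d))` for
#' `X ~ Binomial(theta, 1/2)`.
#'
#' `method = "normal"` uses the normal simplification
#' `P(wrong) = 1 - Phi(w*phi(d) / sqrt(theta))`; `method = "exact"`
#' evaluates the binomial CDFs with `round(theta)` trials, counting half
#' of any boundary point mass as wrong (matching the read operation's
#' fair tie-break).
#'
#' @param params a [theory_params()] object.
#' @param d cue distance in bits.
#' @param method `"normal"` or `"exact"`.
#' @param phi optional phi(d) override.
#' @return P(wrong) in `[0, 1]`.
#' @examples
#' cp <- theory_params(1000, 1e6, 451, s = 1e4, w = 1, h = 1000)
#' 1 - p_wrong(cp, 200, phi = 97) # ~0.835 per-bit correct probability
#' @export
p_wrong <- function(params, d, method = c("normal", "exact"), phi = NULL) {
  stopifnot(inherits(params, "theory_params"))
  method <- match.arg(method)
  phi <- theory_phi(params, d, phi)
  th <- theta(params, d, phi = phi)
  if (any(th <= 0)) stop("theta must be positive")
  signal <- params$w * phi
  if (method == "normal") {
    return(1 - stats::pnorm(signal / sqrt(th)))
  }
  Tt <- params$s * params$h^2 / (2 * params$H)
  size <- round(th)
  alpha <- binom_cdf_half(size, Tt)
  beta <- binom_cdf_half(size, Tt - signal)
  0.5 * ((1 - alpha) + beta)
}

# P(X < t) + 0.5 * P(X == t) for X ~ Binomial(size, 1/2) and a possibly
# non-integer threshold t (half-mass only when t is an integer).
binom_cdf_half <- function(size, t) {
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti < 0) { out[i] <- 0; next }
    if (ti > size) { out[i] <- 1; next }
    fl <- floor(ti + 1e-9)
    if (abs(ti - round(ti)) < 1e-9) {
      out[i] <- stats::pbinom(fl - 1, size, 0.5) +
        0.5 * stats::dbinom(fl, size, 0.5)
    } else {
      out[i] <- stats::pbinom(fl, size, 0.5)
    }
  }
  out
}

#' Critical-distance objective f~(d)
#'
#' `f~(d) = (P(wrong) - d/n)^2` with the normal-approximate P(wrong).
#' Its integer minimizer locates the cue distance at which the expected
#' read output is as far from the target as the cue itself was -- the
#' convergence/divergence boundary.
#'
#' @param params a [theory_params()] object.
#' @param d cue distance in bits.
#' @param phi optional phi(d) override.
#' @return f~(d) >= 0.
#' @examples
#' cp <- theory_params(1000, 1e6, 451, s = 1e4, w = 1, h = 1000)
#' f_tilde(cp, 209, phi = 87) # ~0.00032
#' @export
f_tilde <- function(params, d, phi = NULL) {
  (p_wrong(params, d, method = "normal", phi = phi) - d / params$n)^2
}

#' Locate the critical distance by integer minimization
#'
#' Evaluates the objective f~(d) on every integer d in range (default:
#' all d in `[0, n]` with positive theta).  Because f~ vanishes at every
#' fixed point of `n*P(wrong) = d` -- including the trivial one at the
#' bottom of the convergent basin, where both sides are essentially
#' zero -- the critical distance is the minimizer at the
#' convergence-to-divergence onset: the first bracket of distances
#' (`g(d) < 0`, `g(d') >= 0` for `g(d) = n*P(wrong) - d`) where the
#' expected read-output distance stops shrinking and starts exceeding
#' the cue distance.  `d_star` is the argmin of f~ within that bracket,
#' ties broken toward the smaller d; the full profile and the bracket
#' are returned alongside.  When no onset exists in range (a memory that
#' converges everywhere scanned), the global argmin over positive d is
#' reported and `bracket` is NULL.
#'
#' @param params a [theory_params()] object.
#' @param d_range optional integer vector of distances to scan.
#' @param phi_table optional data frame with columns `d` and `phi`
#'   (e.g. from a published table) overriding the analytic phi at the
#'   listed distances; the scan is then restricted to those distances.
#' @return An object of class `critical_distance`: list with `d_star`,
#'   `bracket` (length-2 integer vector or NULL), `profile` (data frame
#'   with columns d, phi, theta, alpha_t, beta_t, p_wrong, f_tilde) and
#'   `params`.
#' @export
critical_distance <- function(params, d_range = NULL, phi_table = NULL) {
  stopifnot(inherits(params, "theory_params"))
  if (!is.null(phi_table)) {
    stopifnot(is.data.frame(phi_table), all(c("d", "phi") %in%
      names(phi_table)))
    d <- as.integer(phi_table$d)
    phi <- as.numeric(phi_table$phi)
    if (!is.null(d_range)) {
      keep <- d %in% d_range
      d <- d[keep]; phi <- phi[keep]
    }
    o <- order(d); d <- d[o]; phi <- phi[o]
  } else {
    d <- if (is.null(d_range)) 0:params$n else as.integer(sort(d_range))
    phi <- theory_phi(params, d)
  }
  th <- params$s * params$h^2 / params$H - params$w * phi
  valid <- th > 0
  if (!any(valid)) stop("no distance with positive theta in range")
  d <- d[valid]; phi <- phi[valid]; th <- th[valid]
  z <- params$w * phi / sqrt(th)
  alpha_t <- stats::pnorm(z)
  beta_t <- stats::pnorm(-z)
  pw <- 0.5 * ((1 - alpha_t) + beta_t)
  ft <- (pw - d / params$n)^2
  profile <- data.frame(d = d, phi = phi, theta = th,
    alpha_t = alpha_t, beta_t = beta_t, p_wrong = pw, f_tilde = ft)
  g <- params$n * pw - d
  # divergence onset: expected output distance overtakes the cue distance
  cross <- which(g[-length(g)] < 0 & g[-1] >= 0)
  bracket <- NULL
  if (length(cross) > 0) {
    i <- cross[1]
    bracket <- c(d[i], d[i + 1])
    # phi is constant on odd/even parity plateaus, so g zigzags with
    # period 2 near the onset; search one plateau width beyond the
    # sign-change pair for the integer minimizer
    inb <- which(d >= bracket[1] - 1 & d <= bracket[2] + 1)
    d_star <- d[inb[which.min(ft[inb])]] # first index: smaller d on ties
  } else {
    pos <- which(d > 0)
    if (length(pos) == 0) pos <- seq_along(d)
    d_star <- d[pos[which.min(ft[pos])]]
  }
  structure(list(d_star = d_star, bracket = bracket, profile = profile,
    params = params), class = "critical_distance")
}

#' @export
print.critical_distance <- function(x, ...) {
  cat(sprintf("Critical distance: d* = %d (f~ = %.3g)\n", x$d_star,
    x$profile$f_tilde[x$profile$d == x$d_star]))
  if (!is.null(x$bracket)) {
    cat(sprintf("  fixed-point bracket of n*P(wrong) - d: [%d, %d]\n",
      x$bracket[1], x$bracket[2]))
  } else {
    cat("  no sign change of n*P(wrong) - d in range\n")
  }
  cat(sprintf("  scanned %d distances (d in [%d, %d])\n",
    nrow(x$profile), min(x$profile$d), max(x$profile$d)))
  invisible(x)
}

#' @export
plot.critical_distance <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$d, p$f_tilde, type = "l", log = "y",
    xlab = "cue distance d (bits)", ylab = "f~(d)",
    main = "Critical-distance objective", ...)
  graphics::abline(v = x$d_star, col = "blue", lty = 2)
  if (!is.null(x$bracket)) {
    graphics::abline(v = x$bracket, col = "grey60", lty = 3)
  }
  invisible(x)
}
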