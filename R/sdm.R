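#' Configuration of a sparse distributed memory
#'
#' @param n positive integer dimension of the binary space.
#' @param H number of hard locations sampled from \{0,1\}^n.
#' @param r inclusive access radius in bits; exactly one of `r` and
#'   `fraction` must be given.
#' @param fraction target mean activation fraction; the radius is then
#'   chosen with [select_access_radius()].
#' @param seed root seed; all randomness of the memory (hard-location
#'   sample, tie-breaks) derives from it via [stream_seed()].
#' @return An object of class `sdm_config`.
#' @examples
#' sdm_config(256, 1e4, fraction = 1e-3, seed = 1)
#' @export
sdm_config <- function(n, H, r = NULL, fraction = NULL, seed = 1L) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1,
    is.numeric(H), length(H) == 1, H >= 1)
  n <- as.integer(n)
  if (is.null(r) == is.null(fraction)) {
    stop("give exactly one of 'r' and 'fraction'")
  }
  if (is.null(r)) r <- select_access_radius(n, fraction)
  if (r < 0 || r > n) stop("'r' must be in [0, ", n, "]")
  structure(
    list(n = n, H = as.integer(H), r = as.integer(r),
      fraction = if (is.null(fraction)) NA_real_ else fraction,
      seed = as.integer(seed)),
    class = "sdm_config"
  )
}

#' @export
print.sdm_config <- function(x, ...) {
  cat(sprintf("SDM configuration: n = %d, H = %d, r = %d, seed = %d\n",
    x$n, x$H, x$r, x$seed))
  invisible(x)
}

#' Instantiate a sparse distributed memory
#'
#' Samples `H` hard-location addresses i.i.d. uniform over \{0,1\}^n
#' (with replacement; at realistic scales collisions are vanishingly
#' rare) and attaches one signed counter per location per dimension, all
#' zero.  The store has reference semantics: it is an environment, and
#' [sdm_write()] mutates it in place.
#'
#' @param config an [sdm_config()] object.
#' @return An environment of class `sdm` with fields `n`, `H`, `r`,
#'   `seed`, `addresses` (H x n 0/1 matrix), `counters` (H x n signed
#'   matrix), `write_load` (items written per location), `n_writes` and
#'   `tie_counter`.
#' @examples
#' mem <- sdm(sdm_config(64, 200, fraction = 0.01, seed = 1))
#' mem
#' @export
sdm <- function(config) {
  stopifnot(inherits(config, "sdm_config"))
  # two H x n double matrices (addresses + counters)
  bytes <- 2 * 8 * as.double(config$H) * config$n
  if (bytes > getOption("sdmemory.max_bytes", 4e9)) {
    stop("resource-infeasible store: H x n = ", config$H, " x ", config$n,
      " needs ~", round(bytes / 1e9, 1), " GB ",
      "(raise options(sdmemory.max_bytes=) to override)")
  }
  addresses <- with_seed(
    stream_seed(config$seed, "hard-locations"),
    matrix(as.double(stats::rbinom(config$H * config$n, 1L, 0.5)),
      nrow = config$H, ncol = config$n)
  )
  store <- new.env(parent = emptyenv())
  store$n <- config$n
  store$H <- config$H
  store$r <- config$r
  store$seed <- config$seed
  store$addresses <- addresses
  store$addr_ones <- rowSums(addresses)
  store$counters <- matrix(0, nrow = config$H, ncol = config$n)
  store$write_load <- numeric(config$H)
  store$n_writes <- 0L
  store$tie_counter <- 0L
  class(store) <- "sdm"
  store
}

#' @export
print.sdm <- function(x, ...) {
  cat(sprintf(
    "Sparse distributed memory: n = %d, H = %d, r = %d (activates ~%.1f)\n",
    x$n, x$H, x$r, x$H * activation_probability(x$n, x$r)))
  cat(sprintf("  %d write(s); mean items per hard location %.2f\n",
    x$n_writes, mean(x$write_load)))
  invisible(x)
}

#' @export
summary.sdm <- function(object, ...) {
  p <- activation_probability(object$n, object$r)
  out <- list(
    n = object$n, H = object$H, r = object$r,
    activation_probability = p,
    expected_assembly = object$H * p,
    n_writes = object$n_writes,
    mean_items_per_location = mean(object$write_load),
    counter_range = range(object$counters)
  )
  class(out) <- "summary.sdm"
  out
}

#' @export
print.summary.sdm <- function(x, ...) {
  cat(sprintf("SDM n = %d, H = %d, r = %d\n", x$n, x$H, x$r))
  cat(sprintf("  activation probability %.3g (expected assembly %.1f)\n",
    x$activation_probability, x$expected_assembly))
  cat(sprintf("  writes %d; mean items/location %.2f; counters in [%d, %d]\n",
    x$n_writes, x$mean_items_per_location,
    x$counter_range[1], x$counter_range[2]))
  invisible(x)
}

#' Hard locations activated by a probe address
#'
#' The cell assembly of `center`: all hard locations whose address lies
#' within the inclusive Hamming ball of radius `r` around it.
#'
#' @param store an [sdm()] store.
#' @param center bit vector of dimension `store$n`.
#' @return Integer vector of activated location indices (possibly empty).
#' @export
sdm_activate <- function(store, center) {
  center <- check_bitvector(center, "center")
  if (length(center) != store$n) {
    stop("dimension mismatch: probe has ", length(center),
      " bits, memory has ", store$n)
  }
  d <- store$addr_ones + sum(center) -
    2 * as.vector(store$addresses %*% center)
  which(d <= store$r)
}

# Activation sets for many probes at once (items given as rows).
# Returns a list of index vectors.
activate_many <- function(store, items) {
  g <- store$addresses %*% t(items)              # H x m
  ones <- rowSums(items)
  lapply(seq_len(nrow(items)), function(j) {
    which(store$addr_ones + ones[j] - 2 * g[, j] <= store$r)
  })
}

#' Write an item into the memory
#'
#' Distributed write: in every activated hard location, the counter of
#' each dimension is incremented by `times` where the datum bit is 1 and
#' decremented by `times` where it is 0.  The autoassociative convention
#' stores an item at the address equal to itself, which is the default
#' when `datum` is omitted.  `times` models rehearsal: writing with
#' `times = w` is bit-identical to writing the item `w` times.
#'
#' @param store an [sdm()] store (mutated in place).
#' @param address bit vector addressing the write.
#' @param datum bit vector to store; defaults to `address`.
#' @param times positive integer rehearsal count.
#' @return The store, invisibly.
#' @export
sdm_write <- function(store, address, datum = address, times = 1L) {
  address <- check_bitvector(address, "address")
  datum <- check_bitvector(datum, "datum")
  if (length(address) != store$n || length(datum) != store$n) {
    stop("dimension mismatch: memory dimension is ", store$n)
  }
  stopifnot(times >= 1)
  act <- sdm_activate(store, address)
  if (length(act) == 0) {
    warning("write activated no hard locations; store unchanged")
    return(invisible(store))
  }
  delta <- as.double(times) * (2 * datum - 1)
  store$counters[act, ] <- store$counters[act, , drop = FALSE] +
    matrix(delta, nrow = length(act), ncol = store$n, byrow = TRUE)
  store$write_load[act] <- store$write_load[act] + times
  store$n_writes <- store$n_writes + as.integer(times)
  invisible(store)
}

# Batched autoassociative writes: items as rows of an m x n matrix,
# `times` recycled over items.  Bit-identical to sequential sdm_write()
# calls; used by the experiment layer for speed (one BLAS product per
# chunk instead of one per item).
write_many <- function(store, items, times = 1L, chunk = 256L) {
  stopifnot(is.matrix(items), ncol(items) == store$n)
  m <- nrow(items)
  times <- rep_len(as.double(times), m)
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    block <- items[lo:hi, , drop = FALSE]
    acts <- activate_many(store, block)
    empty <- lengths(acts) == 0
    if (any(empty)) {
      warning(sum(empty), " write(s) activated no hard locations")
    }
    ind <- matrix(0, nrow = store$H, ncol = nrow(block))
    for (j in seq_along(acts)) ind[acts[[j]], j] <- times[lo + j - 1L]
    store$counters <- store$counters + ind %*% (2 * block - 1)
    store$write_load <- store$write_load + rowSums(ind)
    store$n_writes <- store$n_writes + as.integer(sum(times[lo:hi]))
  }
  invisible(store)
}

# Majority vote over a prepared activation set; `tie_seed` drives the
# random 0/1 choice on zero counter sums.
read_from_activation <- function(store, act, tie_seed) {
  if (length(act) == 0) {
    s <- numeric(store$n)
  } else {
    s <- colSums(store$counters[act, , drop = FALSE])
  }
  out <- as.integer(s > 0)
  ties <- which(s == 0)
  if (length(ties) > 0) {
    out[ties] <- with_seed(tie_seed,
      as.integer(stats::runif(length(ties)) < 0.5))
  }
  out
}

#' Read from the memory at a cue address
#'
#' Sums, per dimension, the counters of all activated hard locations and
#' returns bit 1 where the sum is positive, 0 where negative, and a fair
#' coin flip where it is exactly zero.  An empty activation set makes
#' every bit a tie (fully random output) and logs a warning.
#'
#' Tie-break randomness comes from the store's dedicated "ties" stream
#' (advancing `store$tie_counter`) unless `seed` is supplied, so write
#' and read reproducibility are decoupled.
#'
#' @param store an [sdm()] store.
#' @param cue bit vector of dimension `store$n`.
#' @param seed optional integer seed for the tie-break draw.
#' @return The read bit vector.
#' @export
sdm_read <- function(store, cue, seed = NULL) {
  cue <- check_bitvector(cue, "cue")
  if (length(cue) != store$n) {
    stop("dimension mismatch: memory dimension is ", store$n)
  }
  act <- sdm_activate(store, cue)
  if (length(act) == 0) {
    warning("read activated no hard locations; output is uniform random")
  }
  if (is.null(seed)) {
    seed <- stream_seed(store$seed, "ties", store$tie_counter)
    store$tie_counter <- store$tie_counter + 1L
  }
  read_from_activation(store, act, seed)
}

# Advance m cues in lockstep through iterated reads.  Dynamics per cue:
# stop "converged" when a read output equals its input (observable fixed
# point), "diverged" when successive iterates jump by at least
# n/2 - 2*sqrt(n/4) bits (an essentially random re-location), else
# "exhausted" at the iteration budget.  Tie seeds derive from
# (seed, cue index, iteration).  With `trajectory = TRUE` (single cue)
# the full iterate matrix is kept.
iterate_cues <- function(store, cues, max_iters = 6L, target = NULL,
                         seed = NULL, trajectory = FALSE) {
  stopifnot(is.matrix(cues), ncol(cues) == store$n, max_iters >= 1)
  m <- nrow(cues)
  if (is.null(seed)) {
    seed <- stream_seed(store$seed, "ties", store$tie_counter)
    store$tie_counter <- store$tie_counter + 1L
  }
  div_thresh <- store$n / 2 - 2 * sqrt(store$n / 4)
  cur <- cues
  verdict <- rep("exhausted", m)
  iters_used <- rep(0L, m)
  alive <- rep(TRUE, m)
  iterates <- if (trajectory) vector("list", max_iters)
  dists <- if (!is.null(target)) vector("list", m)
  for (it in seq_len(max_iters)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    acts <- activate_many(store, cur[idx, , drop = FALSE])
    for (jj in seq_along(idx)) {
      j <- idx[jj]
      if (length(acts[[jj]]) == 0) {
        warning("read activated no hard locations; output is uniform random")
      }
      out <- read_from_activation(store, acts[[jj]],
        stream_seed(seed, j, it))
      step <- sum(out != cur[j, ])
      iters_used[j] <- it
      if (!is.null(target)) dists[[j]] <- c(dists[[j]], sum(out != target))
      if (trajectory) iterates[[it]] <- out
      if (step == 0) {
        verdict[j] <- "converged"
        alive[j] <- FALSE
      } else if (step >= div_thresh) {
        verdict[j] <- "diverged"
        alive[j] <- FALSE
        cur[j, ] <- out
      } else {
        cur[j, ] <- out
      }
    }
  }
  list(
    final = cur,
    verdict = verdict,
    iterations_used = iters_used,
    distances_to_target = dists,
    iterates = if (trajectory) {
      do.call(rbind, iterates[!vapply(iterates, is.null, logical(1))])
    },
    seed = seed
  )
}

#' Iterated reading with convergence/divergence detection
#'
#' Feeds each read output back as the next cue.  The run stops as
#' `converged` when an iterate is an observable fixed point (reading it
#' returns itself -- at the target this coincides with having retrieved
#' the stored item), as `diverged` when successive iterates jump by at
#' least `n/2 - 2*sqrt(n/4)` bits (the iterate has escaped to an
#' essentially random point), and as `exhausted` when the iteration
#' budget runs out.
#'
#' @param store an [sdm()] store.
#' @param cue starting bit vector.
#' @param max_iters iteration budget (default 6; empirically, larger
#'   budgets improve retrieval only marginally beyond 6).
#' @param target optional known target; when given, the distance of each
#'   iterate to it is recorded.
#' @param seed optional integer seed for the tie-break streams.
#' @return An object of class `read_trajectory`: list with `iterates`
#'   (matrix, one read output per row), `distances_to_target` (or NULL),
#'   `verdict` (`"converged"`, `"diverged"` or `"exhausted"`) and
#'   `iterations_used`.
#' @export
iterative_read <- function(store, cue, max_iters = 6L, target = NULL,
                           seed = NULL) {
  cue <- check_bitvector(cue, "cue")
  if (length(cue) != store$n) {
    stop("dimension mismatch: memory dimension is ", store$n)
  }
  if (!is.null(target)) target <- check_bitvector(target, "target")
  res <- iterate_cues(store, matrix(cue, nrow = 1), max_iters = max_iters,
    target = target, seed = seed, trajectory = TRUE)
  structure(
    list(
      iterates = res$iterates,
      distances_to_target = if (!is.null(target)) {
        res$distances_to_target[[1]]
      },
      verdict = res$verdict[1],
      iterations_used = res$iterations_used[1]
    ),
    class = "read_trajectory"
  )
}

#' @export
print.read_trajectory <- function(x, ...) {
  cat(sprintf("Read trajectory: %s after %d iteration(s)\n",
    x$verdict, x$iterations_used))
  if (!is.null(x$distances_to_target)) {
    cat("  distance to target per iterate:",
      paste(x$distances_to_target, collapse = " "), "\n")
  }
  invisible(x)
}
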