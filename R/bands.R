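#' Simulation experiments: the empirical critical band
#'
#' Scaled-down reproductions of the heat-map simulations: populate a
#' memory with one target (written `w` times) plus `s` random items
#' (written once each, all autoassociatively), probe it with cues at a
#' grid of distances, run iterated reads, and locate the band where
#' exact retrieval gives way to divergence.
#'
#' @name critical-band-experiments
NULL

band_log <- function(...) {
  if (isTRUE(getOption("sdmemory.verbose", FALSE))) message(sprintf(...))
}

#' Experiment grid specification
#'
#' @param config an [sdm_config()] giving the memory geometry.
#' @param s_values stored-item counts to sweep.
#' @param w_values target rehearsal counts to sweep.
#' @param iter_budgets iterated-read budgets to sweep.
#' @param cues_per_distance cues probed at each distance.
#' @param distance_step spacing of the probe-distance grid.
#' @param seed root seed for the sweep; every cell derives its own
#'   streams from it, so cells are reproducible in isolation.
#' @return An object of class `experiment_grid`.
#' @export
experiment_grid <- function(config, s_values, w_values = 1L,
                            iter_budgets = 6L, cues_per_distance = 20L,
                            distance_step = 4L, seed = config$seed) {
  stopifnot(inherits(config, "sdm_config"),
    length(s_values) >= 1, length(w_values) >= 1,
    length(iter_budgets) >= 1, cues_per_distance >= 1,
    distance_step >= 1)
  structure(list(config = config, s_values = as.integer(s_values),
    w_values = as.integer(w_values),
    iter_budgets = as.integer(iter_budgets),
    cues_per_distance = as.integer(cues_per_distance),
    distance_step = as.integer(distance_step),
    seed = as.integer(seed)), class = "experiment_grid")
}

#' Estimate the critical band for one (s, w) memory load
#'
#' Procedure: instantiate the store; write the target `w` times and `s`
#' uniform random items once each (autoassociatively, item stored at its
#' own address); at each probe distance generate `cues_per_distance`
#' cues with [make_cue_at_distance()] and run iterated reads with budget
#' `iter_budget`; record exact convergence (final iterate equals the
#' target -- a fixed point at a non-target attractor does not count) and
#' the final distance to the target.
#'
#' Band lines over the probe grid: `green` is the first distance with
#' any non-convergence, `red` the last distance with any exact
#' convergence, and `blue` the empirical critical distance -- the
#' smallest positive distance where the mean final distance is at least
#' the input distance (with a linearly interpolated crossing reported as
#' `blue_interp`).
#'
#' @param config an [sdm_config()].
#' @param s number of random items stored (the target's `w` writes are
#'   in addition to these).
#' @param w target rehearsal count.
#' @param iter_budget iterated-read budget.
#' @param cues_per_distance cues probed per distance.
#' @param distance_step probe-grid spacing in bits.
#' @param seed root seed for this cell (default: the config seed).
#' @return An object of class `critical_band`: `s`, `w`, `iter_budget`,
#'   `green`, `red`, `blue`, `blue_interp` and a `records` data frame
#'   with per-distance counts and means.
#' @export
run_band_cell <- function(config, s, w = 1L, iter_budget = 6L,
                          cues_per_distance = 20L, distance_step = 4L,
                          seed = config$seed) {
  stopifnot(inherits(config, "sdm_config"), s >= 0, w >= 1,
    iter_budget >= 1, cues_per_distance >= 1)
  n <- config$n
  cell_cfg <- sdm_config(n, config$H, r = config$r,
    seed = stream_seed(seed, "store", s, w))
  store <- sdm(cell_cfg)
  target <- random_bitvector(n, seed = stream_seed(seed, "target", s, w))
  sdm_write(store, target, times = w)
  if (s > 0) {
    items <- with_seed(stream_seed(seed, "data", s, w),
      matrix(as.double(stats::rbinom(s * n, 1L, 0.5)), nrow = s, ncol = n))
    write_many(store, items, times = 1L)
  }
  ds <- unique(c(seq(0L, n, by = distance_step), n))
  m <- as.integer(cues_per_distance)
  rec <- data.frame(d = ds, n_cues = m, n_exact = 0L,
    mean_final_distance = NA_real_, convergence_rate = NA_real_,
    n_converged = 0L, n_diverged = 0L, n_exhausted = 0L)
  for (i in seq_along(ds)) {
    d <- ds[i]
    cues <- t(vapply(seq_len(m), function(cix) {
      as.double(make_cue_at_distance(target, d,
        seed = stream_seed(seed, "cues", s, w, d, cix)))
    }, numeric(n)))
    res <- iterate_cues(store, cues, max_iters = iter_budget,
      target = target, seed = stream_seed(seed, "read", s, w, d))
    fd <- rowSums(res$final != matrix(target, m, n, byrow = TRUE))
    rec$n_exact[i] <- sum(fd == 0)
    rec$mean_final_distance[i] <- mean(fd)
    rec$convergence_rate[i] <- mean(fd == 0)
    rec$n_converged[i] <- sum(res$verdict == "converged")
    rec$n_diverged[i] <- sum(res$verdict == "diverged")
    rec$n_exhausted[i] <- sum(res$verdict == "exhausted")
  }
  green <- if (any(rec$n_exact < m)) rec$d[which(rec$n_exact < m)[1]]
    else NA_integer_
  red <- if (any(rec$n_exact > 0)) rec$d[max(which(rec$n_exact > 0))]
    else NA_integer_
  pos <- which(rec$d > 0 & rec$mean_final_distance >= rec$d)
  blue <- if (length(pos) > 0) rec$d[pos[1]] else NA_integer_
  blue_interp <- NA_real_
  if (length(pos) > 0 && pos[1] > 1) {
    i1 <- pos[1]; i0 <- i1 - 1L
    g0 <- rec$mean_final_distance[i0] - rec$d[i0]
    g1 <- rec$mean_final_distance[i1] - rec$d[i1]
    blue_interp <- if (g1 == g0) rec$d[i1] else
      rec$d[i0] + (rec$d[i1] - rec$d[i0]) * (-g0) / (g1 - g0)
  } else if (length(pos) > 0) {
    blue_interp <- as.numeric(blue)
  }
  band_log("band cell s=%d w=%d iters=%d: green=%s red=%s blue=%s",
    s, w, iter_budget, green, red, blue)
  structure(list(s = as.integer(s), w = as.integer(w),
    iter_budget = as.integer(iter_budget), config = config, seed = seed,
    green = green, red = red, blue = blue, blue_interp = blue_interp,
    records = rec), class = "critical_band")
}

#' @export
print.critical_band <- function(x, ...) {
  cat(sprintf(
    "Critical band (s = %d, w = %d, %d iterations, n = %d, H = %d):\n",
    x$s, x$w, x$iter_budget, x$config$n, x$config$H))
  cat(sprintf(
    "  green (first non-convergence) %s | red (last convergence) %s | blue (critical distance) %s\n",
    x$green, x$red, x$blue))
  invisible(x)
}

#' @export
plot.critical_band <- function(x, ...) {
  r <- x$records
  graphics::plot(r$d, r$mean_final_distance, type = "b", pch = 16,
    cex = 0.6, xlab = "cue distance (bits)",
    ylab = "mean final distance to target",
    main = sprintf("Critical band (s = %d, w = %d)", x$s, x$w), ...)
  graphics::abline(0, 1, col = "grey60")
  if (!is.na(x$green)) graphics::abline(v = x$green, col = "green3")
  if (!is.na(x$red)) graphics::abline(v = x$red, col = "red")
  if (!is.na(x$blue)) graphics::abline(v = x$blue, col = "blue")
  invisible(x)
}

band_row <- function(cell) {
  data.frame(s = cell$s, w = cell$w, iters = cell$iter_budget,
    green = cell$green, red = cell$red, blue = cell$blue,
    blue_interp = cell$blue_interp)
}

#' Sweep the iterated-read budget across memory loads
#'
#' Runs [run_band_cell()] for every combination of `s_values` and
#' `iter_budgets` in the grid at the grid's first rehearsal count.  A
#' single read differs sharply from six, while six to forty changes the
#' band only marginally.
#'
#' @param grid an [experiment_grid()].
#' @return A long-format data frame (class `band_table`) with columns
#'   `s`, `w`, `iters`, `green`, `red`, `blue`, `blue_interp`; the
#'   underlying `critical_band` objects are in `attr(, "cells")`.
#' @export
sweep_iteration_budgets <- function(grid) {
  stopifnot(inherits(grid, "experiment_grid"))
  w <- grid$w_values[1]
  cells <- list()
  rows <- list()
  for (s in grid$s_values) {
    for (it in grid$iter_budgets) {
      cell <- run_band_cell(grid$config, s = s, w = w, iter_budget = it,
        cues_per_distance = grid$cues_per_distance,
        distance_step = grid$distance_step, seed = grid$seed)
      cells[[length(cells) + 1L]] <- cell
      rows[[length(rows) + 1L]] <- band_row(cell)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "cells") <- cells
  class(out) <- c("band_table", class(out))
  out
}

#' Sweep the rehearsal count across memory loads
#'
#' Runs [run_band_cell()] over the (s, w) grid at the grid's first
#' iteration budget and appends the theory-predicted critical distance
#' `d_theory` from [critical_distance()] at matching parameters (stored
#' count `s + w`, nominal assembly size from the radius) for
#' side-by-side comparison.
#'
#' @param grid an [experiment_grid()].
#' @return A long-format data frame (class `band_table`) with the band
#'   columns plus `d_theory`; cells in `attr(, "cells")`.
#' @export
sweep_rehearsal <- function(grid) {
  stopifnot(inherits(grid, "experiment_grid"))
  it <- grid$iter_budgets[1]
  cfg <- grid$config
  cells <- list()
  rows <- list()
  for (s in grid$s_values) {
    for (w in grid$w_values) {
      cell <- run_band_cell(cfg, s = s, w = w, iter_budget = it,
        cues_per_distance = grid$cues_per_distance,
        distance_step = grid$distance_step, seed = grid$seed)
      d_theory <- tryCatch({
        pars <- theory_params(cfg$n, cfg$H, cfg$r, s = s + w, w = w)
        critical_distance(pars)$d_star
      }, error = function(e) NA_integer_)
      row <- band_row(cell)
      row$d_theory <- d_theory
      cells[[length(cells) + 1L]] <- cell
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "cells") <- cells
  class(out) <- c("band_table", class(out))
  out
}

#' Export a band sweep as a heat-map matrix CSV
#'
#' One row per (s, w, iters) cell; one column per probe distance holding
#' the chosen metric, plus the green/red/blue overlays as separate
#' columns.
#'
#' @param x a `band_table` (from a sweep), a single `critical_band`, or
#'   a list of `critical_band` objects.
#' @param metric `"mean_final_distance"` or `"convergence_rate"`.
#' @param file optional path; when given the matrix is written as CSV.
#' @return The heat-map data frame, invisibly when `file` is given.
#' @export
export_heatmap <- function(x, metric = c("mean_final_distance",
                           "convergence_rate"), file = NULL) {
  metric <- match.arg(metric)
  cells <- if (inherits(x, "critical_band")) list(x)
    else if (inherits(x, "band_table")) attr(x, "cells")
    else if (is.list(x)) x
    else stop("'x' must be a band table or critical_band object(s)")
  stopifnot(length(cells) >= 1,
    all(vapply(cells, inherits, logical(1), "critical_band")))
  ds <- cells[[1]]$records$d
  rows <- lapply(cells, function(cell) {
    stopifnot(identical(cell$records$d, ds))
    vals <- as.list(cell$records[[metric]])
    names(vals) <- paste0("d_", ds)
    cbind(data.frame(s = cell$s, w = cell$w, iters = cell$iter_budget,
      green = cell$green, red = cell$red, blue = cell$blue),
      as.data.frame(vals))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
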