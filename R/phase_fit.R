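#' Default phase-space grids
#'
#' Logarithmically spaced grids over `C1` in `[1e-5, 5e-3]` and `C2` in
#' `[1e-6, 5e-4]`, covering the fusion-to-fission ratios observed across
#' conditions; log spacing equalizes relative resolution over the two
#' orders of magnitude spanned.
#'
#' @param n number of grid points per axis.
#' @param range numeric length-2 range.
#' @return numeric vector of grid values, strictly increasing.
#' @export
default_c1_grid <- function(n = 12, range = c(1e-5, 5e-3)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' @rdname default_c1_grid
#' @export
default_c2_grid <- function(n = 12, range = c(1e-6, 5e-4)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

# deterministic per-cell seed from the scan key, independent of grid order
cell_seed <- function(master_seed, N, C1, C2, reps) {
  key <- sprintf("%d|%d|%.8e|%.8e|%d", master_seed, N, C1, C2, reps)
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer(h) + 1L
}

#' Scan the (C1, C2) phase space
#'
#' Runs [ff_ensemble()] in every grid cell and records the ensemble mean
#' and standard error of the mean degree and the normalized giant cluster.
#' Cells are seeded deterministically from `(master_seed, N, C1, C2,
#' reps)`, so a scan is reproducible and resumable: with a `cache`
#' directory, completed cells are reloaded instead of re-simulated.
#'
#' @param N number of unit edges per simulation.
#' @param c1_grid,c2_grid strictly increasing grids of rate ratios.
#' @param reps ensemble repetitions per cell.
#' @param master_seed integer seed for the whole scan.
#' @param n_events events per run (default `5 * N`).
#' @param convention propensity convention, see [ff_convention()].
#' @param cache optional directory for per-cell result files.
#' @return an object of class `phase_grid`: a data.frame `cells` with one
#'   row per `(C1, C2)` and the grid metadata.
#' @export
phase_scan <- function(N, c1_grid = default_c1_grid(),
                       c2_grid = default_c2_grid(), reps = 20,
                       master_seed = 1, n_events = 5 * N,
                       convention = "ordered", cache = NULL) {
  stopifnot(length(c1_grid) >= 1, length(c2_grid) >= 1,
            all(diff(c1_grid) > 0) || length(c1_grid) == 1,
            all(diff(c2_grid) > 0) || length(c2_grid) == 1, N >= 1)
  if (!is.null(cache) && !dir.exists(cache)) {
    dir.create(cache, recursive = TRUE)
  }
  rows <- list()
  for (C1 in c1_grid) for (C2 in c2_grid) {
    sd_i <- cell_seed(master_seed, N, C1, C2, reps)
    row <- NULL
    cf <- if (!is.null(cache)) {
      file.path(cache, sprintf("cell_%d_%d_%.6e_%.6e_%d.rds",
                               master_seed, N, C1, C2, reps))
    } else NULL
    if (!is.null(cf) && file.exists(cf)) row <- readRDS(cf)
    if (is.null(row)) {
      en <- ff_ensemble(N, ff_rates(C1, C2, convention = convention),
                        reps = reps, master_seed = sd_i,
                        n_events = n_events)
      row <- data.frame(
        C1 = C1, C2 = C2,
        k_mean = en$mean_degree[["mean"]], k_se = en$mean_degree[["se"]],
        g_mean = en$giant_frac[["mean"]], g_se = en$giant_frac[["se"]],
        reps = reps, N = N, seed = sd_i)
      if (!is.null(cf)) saveRDS(row, cf)
    }
    rows[[length(rows) + 1]] <- row
  }
  structure(list(cells = do.call(rbind, rows),
                 c1_grid = c1_grid, c2_grid = c2_grid,
                 N = as.integer(N), reps = reps,
                 master_seed = master_seed, convention = convention),
            class = "phase_grid")
}

#' @export
print.phase_grid <- function(x, ...) {
  cat("phase-space scan:", length(x$c1_grid), "x", length(x$c2_grid),
      "cells, N =", x$N, ",", x$reps, "reps/cell\n")
  cat(sprintf("  <k> range %.3f-%.3f, N_g/N range %.4f-%.4f\n",
              min(x$cells$k_mean), max(x$cells$k_mean),
              min(x$cells$g_mean), max(x$cells$g_mean)))
  invisible(x)
}

#' Map observed network statistics to (C1, C2)
#'
#' Finds the grid cell whose simulated `(mean degree, N_g/N)` is closest to
#' the observed pair under the relative-error misfit
#' \deqn{((k_{sim}-k_{obs})/k_{obs})^2 + ((g_{sim}-g_{obs})/g_{obs})^2,}
#' (relative errors keep the small giant-cluster fractions from being
#' swamped by the mean degree).  Ties break toward smaller `(C1, C2)`,
#' lexicographically.
#'
#' @param observed numeric `c(mean_degree =, giant_frac =)` (names
#'   optional, order mean degree then giant fraction).
#' @param grid a [phase_scan()] result.
#' @param label optional condition label carried into the result.
#' @return an object of class `fit_result`: fitted `C1`, `C2`, the
#'   `misfit`, the matched cell's statistics, and the grid spacing as a
#'   nearest-cell uncertainty.
#' @export
phase_fit <- function(observed, grid, label = NULL) {
  stopifnot(inherits(grid, "phase_grid"), length(observed) == 2,
            all(is.finite(observed)))
  k_obs <- unname(observed[1]); g_obs <- unname(observed[2])
  cells <- grid$cells
  out_k <- k_obs > max(cells$k_mean + 3 * cells$k_se) |
    k_obs < min(cells$k_mean - 3 * cells$k_se)
  out_g <- g_obs > max(cells$g_mean + 3 * cells$g_se) |
    g_obs < min(cells$g_mean - 3 * cells$g_se)
  if (out_k && out_g) stop("out of phase-space range")
  misfit <- ((cells$k_mean - k_obs) / k_obs)^2 +
    ((cells$g_mean - g_obs) / g_obs)^2
  ord <- order(misfit, cells$C1, cells$C2)
  best <- cells[ord[1], ]
  spacing <- c(
    C1 = if (length(grid$c1_grid) > 1) {
      exp(mean(diff(log(grid$c1_grid))))
    } else NA_real_,
    C2 = if (length(grid$c2_grid) > 1) {
      exp(mean(diff(log(grid$c2_grid))))
    } else NA_real_)
  structure(
    list(label = label, observed = c(mean_degree = k_obs, giant_frac = g_obs),
         C1 = best$C1, C2 = best$C2, misfit = misfit[ord[1]],
         cell = best, grid_step = spacing, N = grid$N,
         convention = grid$convention),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!is.null(x$label)) cat(x$label, ": ", sep = "")
  cat(sprintf("fitted C1 = %.3g, C2 = %.3g (misfit %.4g)\n",
              x$C1, x$C2, x$misfit))
  cat(sprintf("  observed <k> = %.3f, N_g/N = %.4f; cell %.3f, %.4f\n",
              x$observed[1], x$observed[2], x$cell$k_mean, x$cell$g_mean))
  invisible(x)
}

#' Refine a phase-space fit locally
#'
#' Re-scans a finer log-spaced grid around the best cell (one grid step
#' each way) and refits; avoids paying for a globally fine grid.
#'
#' @param fit a [phase_fit()] result.
#' @param grid the [phase_scan()] the fit came from.
#' @param n points per axis in the refined grid.
#' @param reps repetitions per refined cell (default: as the parent scan).
#' @return a new `fit_result` (with the refined `phase_grid` attached as
#'   attribute `grid`).
#' @export
phase_refine <- function(fit, grid, n = 5, reps = grid$reps) {
  step <- fit$grid_step
  r1 <- if (is.na(step["C1"])) rep(fit$C1, 2) else {
    c(fit$C1 / step["C1"], fit$C1 * step["C1"])
  }
  r2 <- if (is.na(step["C2"])) rep(fit$C2, 2) else {
    c(fit$C2 / step["C2"], fit$C2 * step["C2"])
  }
  fine <- phase_scan(grid$N,
                     c1_grid = exp(seq(log(r1[1]), log(r1[2]),
                                       length.out = n)),
                     c2_grid = exp(seq(log(r2[1]), log(r2[2]),
                                       length.out = n)),
                     reps = reps, master_seed = grid$master_seed,
                     convention = grid$convention)
  out <- phase_fit(fit$observed, fine, label = fit$label)
  attr(out, "grid") <- fine
  out
}

#' Compare normal and diseased fitted conditions
#'
#' Emits the fusion-to-fission ratio changes `C1n/C1d` and `C2n/C2d` and
#' the steady-state degree-1/2/3 node fractions of both conditions
#' (measured from fresh ensembles at the fitted parameters), plus the
#' normal/diseased fraction ratios.
#'
#' @param nl,dis `fit_result`s for the normal and diseased condition.
#' @param N_nl,N_dis edges for the two ensembles (default: the fit's grid
#'   `N`).
#' @param reps ensemble repetitions.
#' @param master_seed integer seed.
#' @return a one-row data.frame in the comparison-table schema, with the
#'   two ensembles attached as attributes `ensemble_nl`, `ensemble_dis`.
#' @export
compare_conditions <- function(nl, dis, N_nl = nl$N, N_dis = dis$N,
                               reps = 100, master_seed = 1) {
  stopifnot(inherits(nl, "fit_result"), inherits(dis, "fit_result"))
  en_n <- ff_ensemble(N_nl, ff_rates(nl$C1, nl$C2,
                                     convention = nl$convention),
                      reps = reps, master_seed = master_seed)
  en_d <- ff_ensemble(N_dis, ff_rates(dis$C1, dis$C2,
                                      convention = dis$convention),
                      reps = reps, master_seed = master_seed + 1L)
  fn <- en_n$fractions["mean", ]
  fd <- en_d$fractions["mean", ]
  out <- data.frame(
    condition = nl$label %||% "condition",
    C1n_over_C1d = nl$C1 / dis$C1,
    C2n_over_C2d = nl$C2 / dis$C2,
    X1n = fn[["X1"]], X2n = fn[["X2"]], X3n = fn[["X3"]],
    X1n_over_X1d = fn[["X1"]] / fd[["X1"]],
    X2n_over_X2d = fn[["X2"]] / fd[["X2"]],
    X3n_over_X3d = fn[["X3"]] / fd[["X3"]])
  attr(out, "ensemble_nl") <- en_n
  attr(out, "ensemble_dis") <- en_d
  out
}

#' Distribution comparison between two conditions
#'
#' Pooled loop-size, branch-length and cluster-size distributions of two
#' ensembles, their means with standard errors, and the difference of
#' means (positive = first condition larger, i.e. the second is shifted
#' left).
#'
#' @param nl,dis [ff_ensemble()] results run with `distributions = TRUE`.
#' @return an object of class `distribution_report`: a data.frame `summary`
#'   (rows loops/branches/clusters) and the pooled distributions.
#' @export
distribution_report <- function(nl, dis) {
  stopifnot(inherits(nl, "ff_ensemble"), inherits(dis, "ff_ensemble"))
  need <- c("loop_sizes", "branch_lengths", "cluster_sizes")
  if (!all(need %in% names(nl)) || !all(need %in% names(dis))) {
    stop("ensembles must be run with distributions = TRUE")
  }
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA
  summarize <- function(what) {
    a <- nl[[what]]; b <- dis[[what]]
    data.frame(
      distribution = sub("_.*", "s", what),
      nl_mean = mean(a), nl_se = se(a), nl_n = length(a),
      dis_mean = mean(b), dis_se = se(b), dis_n = length(b),
      shift = mean(a) - mean(b))
  }
  structure(
    list(summary = do.call(rbind, lapply(need, summarize)),
         nl = nl[need], dis = dis[need]),
    class = "distribution_report")
}

#' @export
print.distribution_report <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
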