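#' @useDynLib mitonet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Propensity conventions for the fission-fusion model
#'
#' The model is defined by the two reversible reactions
#' `X1 + X1 <-> X2` (tip-to-tip) and `X1 + X2 <-> X3` (tip-to-side),
#' where `X1`, `X2`, `X3` count network nodes of degree 1, 2 and 3.
#' Fission propensities are always `b1 * X2` and `b2 * X3`.  The fusion
#' propensities are mass-action terms scaled by a convention multiplier:
#'
#' * tip-to-tip fusion: `tt_scale * a1 * X1 * (X1 - 1) / 2`
#' * tip-to-side fusion: `ts_scale * a2 * X1 * X2`
#'
#' Named conventions:
#' * `"pairwise"`: `c(tt = 1, ts = 1)` — textbook counting of unordered
#'   reactant pairs.
#' * `"ordered"`: `c(tt = 2, ts = 1)` — ordered-pair (per-tip encounter)
#'   counting of the tip-to-tip channel.  This is the shipped default: the
#'   original implementation of the model is unpublished and the published
#'   steady-state tables are not mutually consistent under any single
#'   mass-action convention, so the default was selected by an explicit
#'   grid calibration against the published mean-degree and giant-cluster
#'   columns (`scripts/calibration.R`; report in
#'   `inst/extdata/calibration_report.csv`).
#'
#' A bare numeric vector `c(tt = s1, ts = s2)` is accepted anywhere a
#' convention name is.
#'
#' @param convention a convention name or a numeric vector `c(tt=, ts=)`.
#' @return named numeric vector with elements `tt` and `ts`.
#' @export
ff_convention <- function(convention = "ordered") {
  if (is.numeric(convention)) {
    stopifnot(length(convention) == 2, all(convention > 0))
    names(convention) <- c("tt", "ts")
    return(convention)
  }
  presets <- list(
    pairwise = c(tt = 1, ts = 1),
    ordered  = c(tt = 2, ts = 1)
  )
  if (!convention %in% names(presets)) {
    stop("unknown propensity convention: ", convention)
  }
  presets[[convention]]
}

#' Rate parameters for the fission-fusion model
#'
#' Fission rate constants are fixed (`b1 = 0.01`, `b2 = 3 b1 / 2` by
#' default); fusion rates are expressed through the dimensionless
#' fusion-to-fission ratios `C1 = a1/b1` (tip-to-tip) and `C2 = a2/b2`
#' (tip-to-side), the parameters actually fitted to data.
#'
#' @param C1,C2 fusion-to-fission rate ratios, `>= 0`.
#' @param b1 tip-to-tip fission rate constant (per node per unit time).
#' @param b2 tip-to-side fission rate constant; defaults to `1.5 * b1`.
#' @param convention propensity convention, see [ff_convention()].
#' @return an object of class `ff_rates`.
#' @examples
#' ff_rates(C1 = 4.9e-4, C2 = 4.4e-5)
#' @export
ff_rates <- function(C1, C2, b1 = 0.01, b2 = 1.5 * b1,
                     convention = "ordered") {
  stopifnot(C1 >= 0, C2 >= 0, b1 > 0, b2 > 0)
  sc <- ff_convention(convention)
  structure(
    list(C1 = C1, C2 = C2, b1 = b1, b2 = b2,
         a1 = C1 * b1, a2 = C2 * b2,
         tt_scale = unname(sc["tt"]), ts_scale = unname(sc["ts"]),
         convention = if (is.character(convention)) convention else "custom"),
    class = "ff_rates")
}

#' @export
print.ff_rates <- function(x, ...) {
  cat("fission-fusion rates: C1 =", x$C1, " C2 =", x$C2,
      " (b1 =", x$b1, ", b2 =", x$b2, ")\n")
  cat("convention:", x$convention,
      sprintf("[tt_scale = %g, ts_scale = %g]\n", x$tt_scale, x$ts_scale))
  invisible(x)
}

#' Initial simulator state
#'
#' All `2N` tips start unfused: every tip is its own degree-1 node, so
#' `X1 = 2N`, `X2 = X3 = 0`.
#'
#' This R-level state (used by [ff_propensities()] and [ff_step()]) is the
#' reference implementation of the event mechanics; [ff_run()] executes the
#' same model in compiled code.
#'
#' @param N number of unit edges, `>= 1`.
#' @return an object of class `ff_state`.
#' @export
ff_init_state <- function(N) {
  stopifnot(is.numeric(N), length(N) == 1, N >= 1)
  N <- as.integer(N)
  structure(
    list(N = N,
         node_of_tip = seq_len(2L * N),
         tips_of_node = as.list(seq_len(2L * N)),
         time = 0, events = 0L),
    class = "ff_state")
}

#' Species counts of a simulator state
#' @param state an `ff_state`.
#' @return integer vector `c(X1 =, X2 =, X3 =)`.
#' @export
ff_species <- function(state) {
  deg <- lengths(state$tips_of_node)
  c(X1 = sum(deg == 1L), X2 = sum(deg == 2L), X3 = sum(deg == 3L))
}

#' Reaction propensities of a state
#'
#' @param state an `ff_state`.
#' @param rates an [ff_rates()] object.
#' @return numeric vector of the four propensities, in the order
#'   tip-to-tip fusion, tip-to-tip fission, tip-to-side fusion,
#'   tip-to-side fission.
#' @export
ff_propensities <- function(state, rates) {
  x <- ff_species(state)
  c(tt_fusion  = rates$tt_scale * rates$a1 * x[["X1"]] * (x[["X1"]] - 1) / 2,
    tt_fission = rates$b1 * x[["X2"]],
    ts_fusion  = rates$ts_scale * rates$a2 * x[["X1"]] * x[["X2"]],
    ts_fission = rates$b2 * x[["X3"]])
}

#' Execute one Gillespie event (reference implementation)
#'
#' Samples an exponential waiting time from the total propensity, picks a
#' reaction proportionally to its propensity, and picks reactants uniformly
#' among eligible nodes (for tip-to-side fission, the detaching tip is
#' uniform among the three tips of the chosen degree-3 node).  Two tips of
#' the same edge may fuse (forming a unit self-loop); no node ever exceeds
#' degree 3.
#'
#' @param state an `ff_state`.
#' @param rates an [ff_rates()] object.
#' @return the updated `ff_state`; if the total propensity is zero the
#'   state is returned unchanged with attribute `absorbed = TRUE`.
#' @export
ff_step <- function(state, rates) {
  p <- ff_propensities(state, rates)
  total <- sum(p)
  if (total <= 0) {
    attr(state, "absorbed") <- TRUE
    return(state)
  }
  state$time <- state$time + stats::rexp(1, rate = total)
  state$events <- state$events + 1L
  reaction <- sample.int(4L, 1L, prob = p)
  deg <- lengths(state$tips_of_node)
  if (reaction == 1L) {            # tt fusion: X1 + X1 -> X2
    pair <- sample(which(deg == 1L), 2L)
    a <- pair[1]; b <- pair[2]
    tb <- state$tips_of_node[[b]]
    state$tips_of_node[[a]] <- c(state$tips_of_node[[a]], tb)
    state$tips_of_node[[b]] <- integer(0)
    state$node_of_tip[tb] <- a
  } else if (reaction == 2L) {     # tt fission: X2 -> X1 + X1
    a <- resample(which(deg == 2L), 1L)
    t2 <- state$tips_of_node[[a]][2]
    b <- which(deg == 0L)[1]
    state$tips_of_node[[a]] <- state$tips_of_node[[a]][1]
    state$tips_of_node[[b]] <- t2
    state$node_of_tip[t2] <- b
  } else if (reaction == 3L) {     # ts fusion: X1 + X2 -> X3
    a <- resample(which(deg == 1L), 1L)
    b <- resample(which(deg == 2L), 1L)
    ta <- state$tips_of_node[[a]]
    state$tips_of_node[[b]] <- c(state$tips_of_node[[b]], ta)
    state$tips_of_node[[a]] <- integer(0)
    state$node_of_tip[ta] <- b
  } else {                         # ts fission: X3 -> X1 + X2
    a <- resample(which(deg == 3L), 1L)
    k <- sample.int(3L, 1L)
    tk <- state$tips_of_node[[a]][k]
    b <- which(deg == 0L)[1]
    state$tips_of_node[[a]] <- state$tips_of_node[[a]][-k]
    state$tips_of_node[[b]] <- tk
    state$node_of_tip[tk] <- b
  }
  state
}

# sample() with the length-1 surprise removed
resample <- function(x, size) x[sample.int(length(x), size)]

#' Realized network of a simulator state
#'
#' Each of the `N` unit edges connects the nodes currently holding its two
#' tips; self-loops (both tips fused at the same node) and parallel edges
#' are legitimate outcomes of the well-mixed model.
#'
#' @param state an `ff_state`, or the integer node-of-tip assignment
#'   (length `2N`) returned by the compiled run.
#' @return a `MitoGraph` (an igraph multigraph, see [as_mito_graph()]).
#' @export
realized_graph <- function(state) {
  node_of_tip <- if (inherits(state, "ff_state")) state$node_of_tip else state
  stopifnot(length(node_of_tip) %% 2 == 0)
  ids <- match(node_of_tip, sort(unique(node_of_tip)))
  m <- matrix(ids, ncol = 2, byrow = TRUE)
  g <- igraph::graph_from_edgelist(m, directed = FALSE)
  as_mito_graph(g, provenance = "simulated")
}

#' Run the fission-fusion simulation
#'
#' Starts from the all-unfused state and executes `n_events` Gillespie
#' events (default `5 * N`, which empirically reaches the stationary regime;
#' stationarity can be checked by doubling `n_events`).  The final network
#' and the species-fraction trajectory are returned.
#'
#' @param N number of unit edges.
#' @param rates an [ff_rates()] object.
#' @param n_events number of Gillespie events to execute.
#' @param seed optional integer seed (applied via `set.seed`).
#' @param record_every record the species counts every this many events;
#'   `0` disables trajectory recording (the initial state is still kept).
#' @return an object of class `ff_result` with elements `graph`
#'   (the realized `MitoGraph`), `species` (final `X1`, `X2`, `X3`),
#'   `mean_degree`, `giant_frac`, `trajectory` (data.frame with columns
#'   `event`, `time`, `X1`, `X2`, `X3`), `absorbed`, `N`, `seed`.
#' @examples
#' r <- ff_run(50, ff_rates(C1 = 1e-2, C2 = 1e-3), seed = 1)
#' r$mean_degree
#' @export
ff_run <- function(N, rates, n_events = 5 * N, seed = NULL,
                   record_every = max(1L, n_events %/% 200L)) {
  stopifnot(inherits(rates, "ff_rates"), N >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- ff_gillespie_cpp(as.integer(N), rates$a1, rates$b1, rates$a2,
                          rates$b2, rates$tt_scale, rates$ts_scale,
                          as.integer(n_events), as.integer(record_every))
  g <- realized_graph(out$node_of_tip)
  traj <- data.frame(event = out$traj[, 1], time = out$traj_time,
                     X1 = out$traj[, 2], X2 = out$traj[, 3],
                     X3 = out$traj[, 4])
  n_nodes <- out$X1 + out$X2 + out$X3
  structure(
    list(graph = g,
         species = c(X1 = out$X1, X2 = out$X2, X3 = out$X3),
         mean_degree = 2 * N / n_nodes,
         giant_frac = giant_cluster(g)[["giant_frac"]],
         trajectory = traj,
         absorbed = out$absorbed,
         N = as.integer(N), n_events = out$events, seed = seed),
    class = "ff_result")
}

#' @export
print.ff_result <- function(x, ...) {
  cat("fission-fusion run: N =", x$N, "edges,", x$n_events, "events\n")
  cat(sprintf("  <k> = %.4f   N_g/N = %.4f   X = (%d, %d, %d)\n",
              x$mean_degree, x$giant_frac,
              x$species[["X1"]], x$species[["X2"]], x$species[["X3"]]))
  invisible(x)
}

#' Ensemble of independent simulation runs
#'
#' Repeats [ff_run()] `reps` times with per-run seeds drawn
#' deterministically from `master_seed`, and averages the steady-state
#' summaries.  Standard errors are over runs.
#'
#' @inheritParams ff_run
#' @param reps number of independent runs.
#' @param master_seed integer; per-run seeds are derived from it.
#' @param distributions if `TRUE`, pool loop-size, branch-length and
#'   cluster-size distributions across runs (slower; needed for the
#'   distribution reports).
#' @return an object of class `ff_ensemble` with per-run summaries
#'   (`runs`), ensemble means and standard errors (`mean_degree`,
#'   `giant_frac`, `fractions` with rows mean/se), and (optionally) pooled
#'   `loop_sizes`, `branch_lengths`, `cluster_sizes`.
#' @examples
#' e <- ff_ensemble(50, ff_rates(1e-2, 1e-3), reps = 5, master_seed = 1)
#' e$mean_degree
#' @export
ff_ensemble <- function(N, rates, reps = 100, master_seed = 1,
                        n_events = 5 * N, distributions = FALSE) {
  stopifnot(reps >= 1)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, reps)
  k <- gf <- numeric(reps)
  frac <- matrix(NA_real_, reps, 3, dimnames = list(NULL, c("X1", "X2", "X3")))
  loops <- branches <- clusters <- vector("list", reps)
  for (i in seq_len(reps)) {
    r <- ff_run(N, rates, n_events = n_events, seed = seeds[i],
                record_every = 0L)
    k[i] <- r$mean_degree
    gf[i] <- r$giant_frac
    frac[i, ] <- r$species / sum(r$species)
    if (distributions) {
      loops[[i]] <- loop_sizes(r$graph)
      branches[[i]] <- branch_lengths(r$graph)
      clusters[[i]] <- cluster_sizes(r$graph)
    }
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  res <- list(
    N = as.integer(N), rates = rates, reps = reps,
    master_seed = master_seed, seeds = seeds,
    runs = data.frame(seed = seeds, mean_degree = k, giant_frac = gf,
                      X1 = frac[, 1], X2 = frac[, 2], X3 = frac[, 3]),
    mean_degree = c(mean = mean(k), se = se(k)),
    giant_frac = c(mean = mean(gf), se = se(gf)),
    fractions = rbind(mean = colMeans(frac), se = apply(frac, 2, se)))
  if (distributions) {
    res$loop_sizes <- unlist(loops)
    res$branch_lengths <- unlist(branches)
    res$cluster_sizes <- unlist(clusters)
  }
  structure(res, class = "ff_ensemble")
}

#' @export
print.ff_ensemble <- function(x, ...) {
  cat("fission-fusion ensemble: N =", x$N, ",", x$reps, "runs\n")
  cat(sprintf("  <k>    = %.4f (se %.4f)\n",
              x$mean_degree[["mean"]], x$mean_degree[["se"]]))
  cat(sprintf("  N_g/N  = %.4f (se %.4f)\n",
              x$giant_frac[["mean"]], x$giant_frac[["se"]]))
  cat(sprintf("  X1/X2/X3 fractions = %.3f / %.3f / %.3f\n",
              x$fractions["mean", 1], x$fractions["mean", 2],
              x$fractions["mean", 3]))
  invisible(x)
}
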