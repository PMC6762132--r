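#' Mean-field steady state of the fission-fusion model
#'
#' Deterministic mass-action fixed point of the two reversible reactions,
#' used as an independent oracle for the stochastic simulator and as a fast
#' initializer for phase-space fitting.  At the fixed point each reversible
#' channel balances separately, giving
#' \deqn{X_2 = s_{tt} (C_1/2)\, X_1 (X_1 - 1), \qquad
#'       X_3 = s_{ts}\, C_2\, X_1 X_2,}
#' subject to tip conservation \eqn{X_1 + 2 X_2 + 3 X_3 = 2N}, where
#' `s_tt`, `s_ts` are the convention multipliers (see [ff_convention()]).
#' The conservation equation reduces to a cubic in `X1` with exactly one
#' root in `[1, 2N]`, found by bracketed root-finding.
#'
#' @param C1,C2 fusion-to-fission ratios, `>= 0`.
#' @param N number of unit edges.
#' @param convention propensity convention, matching the simulator's.
#' @param tol relative conservation tolerance of the root.
#' @return an object of class `ff_meanfield`: continuous expected counts
#'   `X1`, `X2`, `X3`, node `fractions`, `mean_degree`, and the
#'   conservation `residual`.
#' @examples
#' ff_meanfield(C1 = 4.9e-4, C2 = 4.4e-5, N = 2664)
#' @export
ff_meanfield <- function(C1, C2, N, convention = "ordered",
                         tol = 1e-12) {
  stopifnot(C1 >= 0, C2 >= 0, N >= 1)
  sc <- ff_convention(convention)
  alpha <- unname(sc["tt"]) * C1 / 2
  beta <- unname(sc["ts"]) * C2
  mass <- function(x1) {
    x2 <- alpha * x1 * (x1 - 1)
    x3 <- beta * x1 * x2
    x1 + 2 * x2 + 3 * x3
  }
  twoN <- 2 * N
  if (alpha == 0) {
    x1 <- twoN            # no tip-to-tip fusion: everything stays degree 1
  } else {
    # mass(1) = 1 < 2N and mass(2N) >= 2N, so the root is bracketed
    x1 <- stats::uniroot(function(x) mass(x) - twoN, c(1, twoN),
                         tol = tol * twoN)$root
  }
  x2 <- alpha * x1 * (x1 - 1)
  x3 <- beta * x1 * x2
  nodes <- x1 + x2 + x3
  structure(
    list(X1 = x1, X2 = x2, X3 = x3,
         fractions = c(X1 = x1, X2 = x2, X3 = x3) / nodes,
         mean_degree = twoN / nodes,
         residual = abs(x1 + 2 * x2 + 3 * x3 - twoN),
         C1 = C1, C2 = C2, N = N,
         convention = if (is.character(convention)) convention else "custom"),
    class = "ff_meanfield")
}

#' Mean degree of a mean-field solution
#'
#' `(X1 + 2 X2 + 3 X3) / (X1 + X2 + X3) = 2N / (X1 + X2 + X3)`.
#'
#' @param solution an [ff_meanfield()] solution.
#' @return the mean degree.
#' @export
mean_degree_meanfield <- function(solution) {
  stopifnot(inherits(solution, "ff_meanfield"))
  solution$mean_degree
}

#' @export
print.ff_meanfield <- function(x, ...) {
  cat(sprintf("mean-field fixed point (C1 = %g, C2 = %g, N = %d, %s)\n",
              x$C1, x$C2, x$N, x$convention))
  cat(sprintf("  X1 = %.2f  X2 = %.2f  X3 = %.2f   <k> = %.4f\n",
              x$X1, x$X2, x$X3, x$mean_degree))
  invisible(x)
}
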