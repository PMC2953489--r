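#' Growth brackets of the coupled replicator equations
#'
#' The expected-payoff advantage of the preferred behavior in each population.
#' Partners are drawn from the own population with weight `f` (population 1)
#' or `1 - f` (population 2) and from the other population with the
#' complementary weight; an out-group partner of population 1 shows behavior 1
#' with probability `1 - q`. This gives the affine brackets
#' \deqn{G_1 = f [c_1 p + b_1 (1-p)] + (1-f) [C_1 (1-q) + B_1 q]}
#' \deqn{G_2 = (1-f) [c_2 q + b_2 (1-q)] + f [C_2 (1-p) + B_2 p]}
#' which drive `dp/dt = p (1-p) G1` and `dq/dt = q (1-q) G2`.
#'
#' @param g a [game_params] object.
#' @param p,q state coordinates (vectorized).
#' @return A list with numeric components `G1` and `G2`.
#' @export
growth_brackets <- function(g, p, q) {
  stopifnot(inherits(g, "game_params"))
  f <- g$f
  list(G1 = f * (g$c1 * p + g$b1 * (1 - p)) +
            (1 - f) * (g$C1 * (1 - q) + g$B1 * q),
       G2 = (1 - f) * (g$c2 * q + g$b2 * (1 - q)) +
            f * (g$C2 * (1 - p) + g$B2 * p))
}

#' Right-hand side of the replicator flow
#'
#' @param g a [game_params] object.
#' @param p,q state coordinates (vectorized).
#' @return A list with components `dp` and `dq`.
#' @seealso [growth_brackets()]
#' @export
replicator_rhs <- function(g, p, q) {
  G <- growth_brackets(g, p, q)
  list(dp = p * (1 - p) * G$G1, dq = q * (1 - q) * G$G2)
}

# deSolve-compatible derivative function; clamps the state into the unit
# square before evaluating so roundoff excursions cannot feed back.
.rhs_desolve <- function(t, y, parms) {
  p <- min(max(y[1], 0), 1)
  q <- min(max(y[2], 0), 1)
  d <- replicator_rhs(parms, p, q)
  if (!all(is.finite(c(d$dp, d$dq))))
    stop("non-finite vector field at (p, q) = (", p, ", ", q, ")")
  list(c(d$dp, d$dq))
}

#' Integrate the two-population replicator equations
#'
#' Adaptive-step integration (deSolve, `lsodar`) of the coupled flow from
#' `(p0, q0)`. Integration stops early once the sup-norm of the vector field
#' falls below `eps_conv`; the trajectory is then flagged as converged and its
#' final state recorded as the attractor. States are clamped to the unit
#' square (the square is forward-invariant; clamping only removes roundoff
#' excursions).
#'
#' @param g a [game_params] object.
#' @param p0,q0 initial condition in `[0, 1]`.
#' @param t_end integration horizon (> 0).
#' @param rtol,atol relative and absolute integration tolerances.
#' @param eps_conv convergence threshold on the sup-norm of the vector field.
#' @param n_out number of output time points requested from the solver.
#' @return An object of class `trajectory`: list with `times`, `states` (2-col
#'   matrix `p`, `q`), `converged`, and `attractor` (final state when
#'   converged, otherwise `NULL`).
#' @examples
#' g <- game_params(B = -1, C = -1, f = 0.8)
#' tr <- integrate_replicator(g, 0.5, 0.5, t_end = 100)
#' tr$attractor
#' @export
integrate_replicator <- function(g, p0, q0, t_end = 100,
                                 rtol = 1e-9, atol = 1e-11,
                                 eps_conv = 1e-9, n_out = 201) {
  stopifnot(inherits(g, "game_params"))
  if (t_end <= 0) stop("t_end must be positive")
  if (p0 < -1e-12 || p0 > 1 + 1e-12 || q0 < -1e-12 || q0 > 1 + 1e-12)
    stop("initial condition must lie in the unit square")
  p0 <- min(max(p0, 0), 1)
  q0 <- min(max(q0, 0), 1)

  d0 <- replicator_rhs(g, p0, q0)
  if (max(abs(c(d0$dp, d0$dq))) < eps_conv) {
    return(structure(list(times = 0, states = cbind(p = p0, q = q0),
                          converged = TRUE, attractor = c(p = p0, q = q0)),
                     class = "trajectory"))
  }

  rootfun <- function(t, y, parms) {
    d <- .rhs_desolve(t, y, parms)[[1]]
    max(abs(d)) - eps_conv
  }
  times <- seq(0, t_end, length.out = max(2, n_out))
  sol <- deSolve::lsodar(y = c(p0, q0), times = times, func = .rhs_desolve,
                         parms = g, rtol = rtol, atol = atol,
                         rootfunc = rootfun)
  states <- sol[, 2:3, drop = FALSE]
  states[states < 0] <- 0
  states[states > 1] <- 1
  colnames(states) <- c("p", "q")
  final <- states[nrow(states), ]
  dfin <- replicator_rhs(g, final[1], final[2])
  converged <- max(abs(c(dfin$dp, dfin$dq))) < eps_conv
  structure(list(times = sol[, 1], states = states, converged = converged,
                 attractor = if (converged) c(p = unname(final[1]),
                                              q = unname(final[2])) else NULL),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat("Replicator trajectory:", n, "recorded states, t in [0,",
      format(max(x$times)), "]\n")
  if (x$converged)
    cat(sprintf("  converged to attractor (p, q) = (%.6f, %.6f)\n",
                x$attractor[1], x$attractor[2]))
  else
    cat("  not converged within the integration horizon\n")
  invisible(x)
}

#' Locate the attractor reached from an initial condition
#'
#' Runs [integrate_replicator()] with an escalating horizon until the
#' convergence threshold on the vector-field sup-norm is reached or the time
#' budget is exhausted. Non-convergence is reported, never silently rounded to
#' the nearest fixed point.
#'
#' @param g a [game_params] object.
#' @param p0,q0 initial condition.
#' @param horizons increasing integration horizons tried in turn.
#' @param ... passed to [integrate_replicator()] (`rtol`, `atol`, `eps_conv`).
#' @return A list with `attractor` (named vector `p`, `q`; final state even if
#'   unconverged), `converged`, and `t_used`.
#' @examples
#' g <- game_params(B = 1, C = 1, f = 0.8)  # harmony game
#' find_attractor(g, 0.1, 0.1)$attractor    # (1, 1)
#' @export
find_attractor <- function(g, p0, q0, horizons = c(1e2, 1e3, 1e4), ...) {
  last <- NULL
  for (h in sort(horizons)) {
    last <- integrate_replicator(g, p0, q0, t_end = h, ...)
    if (last$converged) {
      return(list(attractor = last$attractor, converged = TRUE, t_used = h))
    }
  }
  final <- last$states[nrow(last$states), ]
  list(attractor = c(p = unname(final[1]), q = unname(final[2])),
       converged = FALSE, t_used = max(horizons))
}

#' Write a trajectory to CSV, with a JSON summary
#'
#' @param tr a `trajectory` object.
#' @param csv path for the time-series CSV (columns `t`, `p`, `q`); `NULL` to
#'   skip.
#' @param json path for a JSON summary (`converged`, `attractor`, `steps`);
#'   `NULL` to skip.
#' @return Invisibly, the summary list.
#' @export
write_trajectory <- function(tr, csv = NULL, json = NULL) {
  stopifnot(inherits(tr, "trajectory"))
  if (!is.null(csv)) {
    write.csv(data.frame(t = tr$times, p = tr$states[, "p"],
                         q = tr$states[, "q"]),
              csv, row.names = FALSE)
  }
  summary <- list(converged = tr$converged,
                  attractor = if (tr$converged) as.list(tr$attractor) else NULL,
                  steps = length(tr$times))
  if (!is.null(json))
    jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                         null = "null")
  invisible(summary)
}
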