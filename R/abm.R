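#' Finite-population agent state
#'
#' Counts of behavior adopters for the stochastic proportional-imitation
#' counterpart of the replicator flow: `k1` of the `N1` population-1 agents
#' show behavior 1, `k2` of the `N2` population-2 agents show behavior 2, so
#' the empirical state is `(p, q) = (k1/N1, k2/N2)`.
#'
#' @param N1,N2 population sizes (`>= 2`).
#' @param k1,k2 adopter counts, `0 <= k <= N`.
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(N1, N2, k1, k2) {
  stopifnot(N1 >= 2, N2 >= 2, k1 >= 0, k1 <= N1, k2 >= 0, k2 <= N2)
  structure(list(N1 = as.integer(N1), N2 = as.integer(N2),
                 k1 = as.integer(k1), k2 = as.integer(k2)),
            class = "agent_state")
}

#' Expected payoff of a pure behavior at the current state
#'
#' Mixes the in-group and out-group payoff rows with weights `(f, 1 - f)` for
#' population 1 and `(1 - f, f)` for population 2, using the payoff matrices
#' anchored at `T = P = 0` (see [payoff_matrices()]). The behavior-difference
#' of this quantity equals the growth bracket `G1` (population 1) or `G2`
#' (population 2).
#'
#' @param g a [game_params] object.
#' @param population 1 or 2.
#' @param behavior 1 or 2, in the global labeling (population 1 prefers
#'   behavior 1, population 2 prefers behavior 2).
#' @param p,q state coordinates.
#' @return The expected payoff (numeric scalar).
#' @export
expected_payoff <- function(g, population, behavior, p, q) {
  stopifnot(inherits(g, "game_params"),
            population %in% c(1, 2), behavior %in% c(1, 2))
  m <- payoff_matrices(g)
  if (population == 1) {
    # own-frame: cooperative behavior of population 1 is behavior 1
    row <- if (behavior == 1) "coop" else "defect"
    f <- g$f
    f * (m$in1[row, "coop"] * p + m$in1[row, "defect"] * (1 - p)) +
      (1 - f) * (m$out1[row, "coop"] * (1 - q) + m$out1[row, "defect"] * q)
  } else {
    # own-frame: cooperative behavior of population 2 is behavior 2
    row <- if (behavior == 2) "coop" else "defect"
    f <- g$f
    (1 - f) * (m$in2[row, "coop"] * q + m$in2[row, "defect"] * (1 - q)) +
      f * (m$out2[row, "coop"] * (1 - p) + m$out2[row, "defect"] * p)
  }
}

# Maximal payoff difference over the unit square: the brackets are affine,
# so the extrema sit at the corners.
.delta_max <- function(g) {
  k <- .bracket_coefs(g)
  corners <- expand.grid(p = c(0, 1), q = c(0, 1))
  g1 <- abs(k$a1 + k$u1 * corners$p + k$v1 * corners$q)
  g2 <- abs(k$a2 + k$u2 * corners$p + k$v2 * corners$q)
  max(g1, g2)
}

#' One elementary proportional-imitation step
#'
#' Asynchronous update: a population is chosen with probability proportional
#' to its size, a focal and a model agent are drawn uniformly without
#' replacement from it, and the focal adopts the model's behavior with
#' probability `max(0, dE) / dmax`, where `dE` is the model-minus-focal
#' expected-payoff difference at the current state and `dmax` the maximal
#' payoff difference over the parameter set. Imitation occurs only within a
#' population. A degenerate game (`dmax = 0`) makes the step an identity.
#'
#' This R implementation defines the chain's semantics; [abm_run()] executes
#' the same chain in compiled code.
#'
#' @param a an [agent_state].
#' @param g a [game_params] object.
#' @return The updated `agent_state`.
#' @export
abm_step <- function(a, g) {
  stopifnot(inherits(a, "agent_state"), inherits(g, "game_params"))
  dmax <- .delta_max(g)
  p <- a$k1 / a$N1; q <- a$k2 / a$N2
  pop1 <- runif(1) < a$N1 / (a$N1 + a$N2)
  N <- if (pop1) a$N1 else a$N2
  k <- if (pop1) a$k1 else a$k2
  focal_coop <- runif(1) < k / N
  model_coop <- runif(1) < (k - focal_coop) / (N - 1)
  if (model_coop == focal_coop || dmax <= 0) return(a)
  G <- growth_brackets(g, p, q)
  G <- if (pop1) G$G1 else G$G2
  dE <- if (model_coop) G else -G
  if (dE > 0 && runif(1) < dE / dmax) {
    d <- if (model_coop) 1L else -1L
    if (pop1) a$k1 <- a$k1 + d else a$k2 <- a$k2 + d
  }
  a
}

#' Run the proportional-imitation chain
#'
#' Executes the chain of [abm_step()] in compiled code for `n_generations`
#' generations, one generation being `N1 + N2` elementary steps (aligning the
#' chain's clock with the replicator time scale up to the factor `dmax`).
#' Runs are bitwise-reproducible under a fixed seed.
#'
#' @param a0 initial [agent_state].
#' @param g a [game_params] object.
#' @param n_generations number of generations to simulate.
#' @param record_every record the empirical state every this many generations.
#' @param seed optional integer seed (applied via [set.seed()]).
#' @param mutation per-step probability of adopting a uniformly random
#'   behavior instead of imitating (default 0, matching the deterministic
#'   model, which has no exploration noise).
#' @return An object of class `abm_series`: data frame with columns
#'   `generation`, `p_hat`, `q_hat`; attributes carry the parameters and
#'   sizes.
#' @examples
#' g <- game_params(B = 1, C = 1, f = 0.5)
#' run <- abm_run(agent_state(200, 200, 40, 40), g, 50, seed = 1)
#' tail(run, 1)   # near (1, 1): the harmony-game attractor
#' @export
abm_run <- function(a0, g, n_generations, record_every = 1, seed = NULL,
                    mutation = 0) {
  stopifnot(inherits(a0, "agent_state"), inherits(g, "game_params"),
            n_generations >= 1, record_every >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- .bracket_coefs(g)
  m <- abm_run_cpp(a0$N1, a0$N2, a0$k1, a0$k2,
                   c(k$a1, k$u1, k$v1, k$a2, k$u2, k$v2),
                   .delta_max(g),
                   as.integer(n_generations), as.integer(record_every),
                   mutation)
  out <- data.frame(generation = m[, 1], p_hat = m[, 2], q_hat = m[, 3])
  structure(out, params = g, N1 = a0$N1, N2 = a0$N2, seed = seed,
            class = c("abm_series", "data.frame"))
}

#' Write an ABM time series and its run manifest
#'
#' @param run an `abm_series`.
#' @param csv path for the CSV time series; `NULL` to skip.
#' @param json path for the JSON manifest (seed, parameters, sizes); `NULL`
#'   to skip.
#' @return Invisibly, the manifest list.
#' @export
write_abm_run <- function(run, csv = NULL, json = NULL) {
  stopifnot(inherits(run, "abm_series"))
  if (!is.null(csv)) write.csv(as.data.frame(run), csv, row.names = FALSE)
  g <- attr(run, "params")
  manifest <- list(seed = attr(run, "seed"),
                   N1 = attr(run, "N1"), N2 = attr(run, "N2"),
                   params = unclass(g))
  if (!is.null(json))
    jsonlite::write_json(manifest, json, auto_unbox = TRUE, digits = NA,
                         null = "null")
  invisible(manifest)
}
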