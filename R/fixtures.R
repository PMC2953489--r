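#' Scenario fixtures for the published phase portraits
#'
#' Returns the parameter sets of the reference phase portraits as named
#' fixtures, each with its `game_params`, representative initial conditions,
#' and the expected attractor(s) — every expected attractor is re-derivable by
#' [find_attractor()] from the listed starts.
#'
#' Shorthand fixtures (in-group equal to out-group parameters):
#' \describe{
#'   \item{fig2A}{`B = C = -1, f = 0.8` — two-population prisoner's dilemma,
#'     breakdown at (0, 0).}
#'   \item{fig2B}{`B = C = 1, f = 0.8` — harmony game, subcultures at (1, 1).}
#'   \item{fig3A}{`B = -1, C = 1, f = 0.8` — stag hunt, |B| = |C|.}
#'   \item{fig3B}{`B = -1, C = 2, f = 0.5` — stag hunt, equal powers; three
#'     coexisting basins.}
#'   \item{fig3C}{`B = -1, C = 2, f = 0.8`.}
#'   \item{fig3D}{`B = -2, C = 1, f = 0.8`.}
#'   \item{fig5A}{`B = 1, C = -1, f = 0.8` — snowdrift, |B| = |C|: stable
#'     equilibrium continuum.}
#'   \item{fig5B}{`B = 1, C = -2, f = 0.5` — snowdrift, equal powers:
#'     breakdown.}
#'   \item{fig5C}{`B = 1, C = -2, f = 0.8` — tacit-alliance attractor
#'     (1/6, 0).}
#'   \item{fig5D}{`B = 2, C = -1, f = 0.8` — post-revolution attractor
#'     (5/6, 1).}
#'   \item{fig7A}{prisoner's dilemma `B = -1, C = -2, f = 0.8` transformed by
#'     costly punishment with cost 2.5 and fine 12.5 (five times the cost) in
#'     both populations; three stable points (0, 0), (1, 0), (0, 1).}
#'   \item{fig7B}{population 1 stag hunt (`B = -1, C = 2`), population 2
#'     prisoner's dilemma (`B = -1, C = -2`), `f = 0.5`; norm at (1, 0).}
#' }
#'
#' @return Named list of fixtures; each element has `name`, `params`,
#'   optionally `punishment`, `starts` (matrix of initial conditions), and
#'   `expected` (matrix of attractors, row-matched to `starts`).
#' @export
scenario_fixtures <- function() {
  sh <- function(B, C, f) game_params(B = B, C = C, f = f)
  fx <- list(
    fig2A = list(params = sh(-1, -1, 0.8),
                 starts = rbind(c(0.5, 0.5), c(0.9, 0.9)),
                 expected = rbind(c(0, 0), c(0, 0))),
    fig2B = list(params = sh(1, 1, 0.8),
                 starts = rbind(c(0.5, 0.5), c(0.1, 0.1)),
                 expected = rbind(c(1, 1), c(1, 1))),
    fig3A = list(params = sh(-1, 1, 0.8),
                 starts = rbind(c(0.95, 0.05), c(0.05, 0.95)),
                 expected = rbind(c(1, 0), c(0, 1))),
    fig3B = list(params = sh(-1, 2, 0.5),
                 starts = rbind(c(0.5, 0.5), c(0.95, 0.05), c(0.05, 0.95)),
                 expected = rbind(c(1, 1), c(1, 0), c(0, 1))),
    fig3C = list(params = sh(-1, 2, 0.8),
                 starts = rbind(c(0.9, 0.1)),
                 expected = rbind(c(1, 0))),
    fig3D = list(params = sh(-2, 1, 0.8),
                 starts = rbind(c(0.95, 0.05)),
                 expected = rbind(c(1, 0))),
    fig5A = list(params = sh(1, -1, 0.8),
                 starts = rbind(c(0.5, 0.5)),
                 expected = NULL),  # converges onto the equilibrium continuum
    fig5B = list(params = sh(1, -2, 0.5),
                 starts = rbind(c(0.5, 0.5)),
                 expected = rbind(c(0, 0))),
    fig5C = list(params = sh(1, -2, 0.8),
                 starts = rbind(c(0.5, 0.5)),
                 expected = rbind(c(1 / 6, 0))),
    fig5D = list(params = sh(2, -1, 0.8),
                 starts = rbind(c(0.5, 0.5)),
                 expected = rbind(c(5 / 6, 1))),
    fig7A = list(params = apply_punishment(sh(-1, -2, 0.8),
                                           punishment_params(gamma = 2.5,
                                                             beta = 12.5)),
                 punishment = punishment_params(gamma = 2.5, beta = 12.5),
                 base_params = sh(-1, -2, 0.8),
                 starts = rbind(c(0.95, 0.05), c(0.05, 0.95), c(0.1, 0.1)),
                 expected = rbind(c(1, 0), c(0, 1), c(0, 0))),
    fig7B = list(params = game_params(f = 0.5,
                                      b1 = -1, c1 = 2, B1 = -1, C1 = 2,
                                      b2 = -1, c2 = -2, B2 = -1, C2 = -2),
                 starts = rbind(c(0.5, 0.5)),
                 expected = rbind(c(1, 0)))
  )
  for (nm in names(fx)) fx[[nm]]$name <- nm
  fx
}

#' Movie-style parameter sweep along C = -B^3
#'
#' The published sweep varies `B` over `[-1.5, 1.5]` with `C = -B^3`, so the
#' game passes through the stag hunt (`B < 0`, `C > 0`) and snowdrift
#' (`B > 0`, `C < 0`) quadrants and through `|B| = |C|` at `|B| = 1`, where
#' the snowdrift branch shows the discontinuous transition of the weaker
#' population. Three interaction structures are available: `"full"` (in-group
#' and out-group parameters equal), `"in_group_only"` (out-group parameters
#' zero: the populations decouple), and `"out_group_only"` (in-group
#' parameters zero: battle-of-the-sexes structure).
#'
#' @param f power of population 1.
#' @param n number of sweep values.
#' @param B_range range of `B` values.
#' @param structure interaction structure, see above.
#' @param p0,q0 start used at every sweep value.
#' @param ... passed to [find_attractor()].
#' @return A `sweep_result` (see [sweep_attractor()]).
#' @export
movie_sweep <- function(f = 0.8, n = 101, B_range = c(-1.5, 1.5),
                        structure = c("full", "in_group_only",
                                      "out_group_only"),
                        p0 = 0.5, q0 = 0.5, ...) {
  structure <- match.arg(structure)
  mk <- switch(structure,
    full = function(B) game_params(B = B, C = -B^3, f = f),
    in_group_only = function(B) game_params(f = f,
      b1 = B, c1 = -B^3, b2 = B, c2 = -B^3, B1 = 0, C1 = 0, B2 = 0, C2 = 0),
    out_group_only = function(B) game_params(f = f,
      b1 = 0, c1 = 0, b2 = 0, c2 = 0, B1 = B, C1 = -B^3, B2 = B, C2 = -B^3))
  vals <- seq(B_range[1], B_range[2], length.out = n)
  vals <- vals[abs(vals) > 1e-9]  # B = 0 is degenerate
  sweep_attractor(vals, mk, p0 = p0, q0 = q0, param_name = "B", ...)
}
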