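# Distance from a point to the continuum segment (if any); Inf when absent.
.continuum_distance <- function(continuum, p, q) {
  if (is.null(continuum)) return(Inf)
  e <- continuum$endpoints
  a <- e[1, ]; b <- e[2, ]
  ab <- b - a
  tt <- sum((c(p, q) - a) * ab) / sum(ab * ab)
  tt <- min(max(tt, 0), 1)
  proj <- a + tt * ab
  sqrt(sum((c(p, q) - proj)^2))
}

#' Outcome label for an attractor state
#'
#' Names the social interpretation of an attractor in the incompatible-
#' preferences model: `"norm_pop1"` for (1, 0) (everyone adopts population 1's
#' preferred behavior), `"norm_pop2"` for (0, 1), `"subcultures"` for (1, 1)
#' (each population keeps its own behavior), `"breakdown"` for (0, 0),
#' `"continuum"` when the state lies on an equilibrium continuum,
#' `"mixed_edge"` for any other fixed point, and `"unresolved"` when the
#' trajectory did not converge.
#'
#' @param p,q attractor coordinates.
#' @param eq an `equilibrium_set` (used for the continuum and other fixed
#'   points); may be `NULL`.
#' @param converged logical; unconverged endpoints are always `"unresolved"`.
#' @param match_tol matching tolerance.
#' @return A character label.
#' @export
outcome_label <- function(p, q, eq = NULL, converged = TRUE,
                          match_tol = 1e-3) {
  if (!converged) return("unresolved")
  corners <- rbind(norm_pop1 = c(1, 0), norm_pop2 = c(0, 1),
                   subcultures = c(1, 1), breakdown = c(0, 0))
  d <- sqrt((corners[, 1] - p)^2 + (corners[, 2] - q)^2)
  if (min(d) < match_tol) return(rownames(corners)[which.min(d)])
  if (!is.null(eq)) {
    if (.continuum_distance(eq$continuum, p, q) < match_tol)
      return("continuum")
    for (fp in eq$points)
      if (sqrt((fp$p - p)^2 + (fp$q - q)^2) < match_tol)
        return("mixed_edge")
  }
  "mixed_edge"
}

#' Map the basins of attraction over the unit square
#'
#' Integrates the replicator flow from each point of an `n` x `n` lattice of
#' initial conditions (edges and corners included; they are invariant and
#' label themselves) and labels each cell by the reached attractor. Cells
#' whose trajectory fails to converge within the horizon budget are labeled
#' `"unresolved"`, never nearest-matched.
#'
#' @param g a [game_params] object.
#' @param n lattice size per axis (`>= 3`).
#' @param eq optional `equilibrium_set`; computed from `g` when missing.
#' @param match_tol attractor-matching tolerance.
#' @param ... passed to [find_attractor()].
#' @return An object of class `basin_grid`: a data frame with columns `p0`,
#'   `q0`, `p_star`, `q_star`, `label`, plus attributes `params` and `eq`.
#' @examples
#' bg <- basin_map(game_params(B = -1, C = -1, f = 0.8), n = 5)
#' table(bg$label)   # all interior cells end in breakdown
#' @export
basin_map <- function(g, n = 21, eq = NULL, match_tol = 1e-3, ...) {
  stopifnot(inherits(g, "game_params"), n >= 3)
  if (is.null(eq)) eq <- enumerate_fixed_points(g)
  lat <- seq(0, 1, length.out = n)
  grid <- expand.grid(p0 = lat, q0 = lat)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    fa <- find_attractor(g, grid$p0[i], grid$q0[i], ...)
    data.frame(p0 = grid$p0[i], q0 = grid$q0[i],
               p_star = fa$attractor["p"], q_star = fa$attractor["q"],
               label = outcome_label(fa$attractor["p"], fa$attractor["q"],
                                     eq, fa$converged, match_tol))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, params = g, eq = eq, class = c("basin_grid", "data.frame"))
}

#' Plot a basin grid as a colored lattice
#'
#' @param x a `basin_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.basin_grid <- function(x, ...) {
  labs <- c("breakdown", "norm_pop1", "norm_pop2", "subcultures",
            "continuum", "mixed_edge", "unresolved")
  cols <- c("firebrick", "forestgreen", "steelblue", "gold",
            "orchid", "grey60", "black")
  lat <- sort(unique(x$p0))
  z <- matrix(match(x$label, labs), nrow = length(lat))
  graphics::image(lat, sort(unique(x$q0)), z, col = cols[sort(unique(c(z)))],
                  xlab = "p(0)", ylab = "q(0)", ...)
  invisible(x)
}

#' Population-weighted overall fraction of cooperative individuals
#'
#' Returns `f p + (1 - f)(1 - q)`: the fraction of all individuals showing
#' behavior 1, i.e. cooperative from population 1's viewpoint. At the stable
#' attractor of the multi-population snowdrift game with unequal powers this
#' equals the one-population expectation `|B| / (|B| + |C|)` of the stronger
#' population exactly.
#'
#' @param g a [game_params] object.
#' @param p,q state coordinates.
#' @return The overall cooperation fraction.
#' @export
overall_cooperation <- function(g, p, q) {
  stopifnot(inherits(g, "game_params"))
  g$f * p + (1 - g$f) * (1 - q)
}

#' Sweep a parameter and record the reached attractor
#'
#' For each value of the swept parameter, builds a parameter set via
#' `make_params`, runs the flow from the fixed start `(p0, q0)` to
#' convergence, and records the attractor and its outcome label. Used for
#' phase-diagram movies (e.g. `C = -B^3` sweeps) and revolutionary-transition
#' detection.
#'
#' @param values strictly monotone numeric vector of parameter values.
#' @param make_params function mapping one value to a [game_params] object.
#' @param p0,q0 initial condition used at every sweep value.
#' @param param_name name of the swept parameter (bookkeeping only).
#' @param ... passed to [find_attractor()].
#' @return An object of class `sweep_result`: data frame with columns `value`,
#'   `p_star`, `q_star`, `converged`, `label`.
#' @examples
#' sr <- sweep_attractor(seq(0.5, 2, by = 0.5),
#'                       function(B) game_params(B = B, C = -1, f = 0.8),
#'                       p0 = 0.5, q0 = 0.5, param_name = "B")
#' @export
sweep_attractor <- function(values, make_params, p0 = 0.5, q0 = 0.5,
                            param_name = "param", ...) {
  if (length(values) < 1 || is.unsorted(values) && is.unsorted(rev(values)))
    stop("values must be strictly monotone")
  rows <- lapply(values, function(v) {
    g <- make_params(v)
    eq <- enumerate_fixed_points(g)
    fa <- find_attractor(g, p0, q0, ...)
    data.frame(value = v,
               p_star = unname(fa$attractor["p"]),
               q_star = unname(fa$attractor["q"]),
               converged = fa$converged,
               label = outcome_label(fa$attractor["p"], fa$attractor["q"],
                                     eq, fa$converged))
  })
  out <- do.call(rbind, rows)
  structure(out, param_name = param_name, start = c(p = p0, q = q0),
            class = c("sweep_result", "data.frame"))
}

#' Detect discontinuous transitions along a sweep
#'
#' Scans a [sweep_attractor()] record for jumps of an attractor coordinate
#' larger than `jump_tol` between adjacent parameter values — the signature of
#' a discontinuous ("revolutionary") transition such as the 0-to-1 jump of the
#' weaker population's equilibrium coordinate when `|B|/|C|` crosses 1 in the
#' multi-population snowdrift game.
#'
#' @param sr a `sweep_result`.
#' @param coordinate `"q_star"` (default) or `"p_star"`.
#' @param jump_tol minimum coordinate change that counts as a jump.
#' @return A data frame with one row per detected jump: `value_lo`,
#'   `value_hi`, `before`, `after`, `jump`.
#' @export
detect_discontinuity <- function(sr, coordinate = c("q_star", "p_star"),
                                 jump_tol = 0.5) {
  coordinate <- match.arg(coordinate)
  stopifnot(inherits(sr, "sweep_result"), nrow(sr) >= 2)
  x <- sr[[coordinate]]
  jumps <- which(abs(diff(x)) > jump_tol)
  data.frame(value_lo = sr$value[jumps], value_hi = sr$value[jumps + 1],
             before = x[jumps], after = x[jumps + 1],
             jump = diff(x)[jumps])
}

#' Norm phase diagram over power and benefit ratio
#'
#' For each combination of power `f` and benefit ratio `b/c`, builds the
#' shorthand parameter set through the benefit/coordination parametrization
#' (`B = b - c`, `C = b + c`, with `c = 1`), starts the flow at
#' `(1 - epsilon, 1 - epsilon)` — everyone initially showing their preferred
#' behavior, infinitesimally perturbed because (1, 1) is itself a fixed
#' point — and records the outcome label. For `b/c >= 1` individuals always
#' keep their own preference (subcultures); for `b/c < 1` a sufficiently
#' strong population sets a shared norm.
#'
#' @param f_values powers of population 1, each in (0, 1).
#' @param b_over_c_values benefit ratios `b/c` (with `c = 1`).
#' @param epsilon initial perturbation away from (1, 1).
#' @param ... passed to [find_attractor()].
#' @return Data frame with columns `f`, `b_over_c`, `p_star`, `q_star`,
#'   `label`.
#' @export
phase_diagram_norms <- function(f_values, b_over_c_values, epsilon = 1e-3,
                                ...) {
  stopifnot(all(f_values > 0 & f_values < 1), epsilon > 0)
  rows <- list()
  for (f in f_values) for (r in b_over_c_values) {
    bc <- params_from_benefit_coordination(b = r, c = 1)
    g <- game_params(B = bc$B, C = bc$C, f = f)
    eq <- enumerate_fixed_points(g)
    fa <- find_attractor(g, 1 - epsilon, 1 - epsilon, ...)
    rows[[length(rows) + 1]] <-
      data.frame(f = f, b_over_c = r,
                 p_star = unname(fa$attractor["p"]),
                 q_star = unname(fa$attractor["q"]),
                 label = outcome_label(fa$attractor["p"], fa$attractor["q"],
                                       eq, fa$converged))
  }
  do.call(rbind, rows)
}
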