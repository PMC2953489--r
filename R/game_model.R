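#' Model parameters for the two-population game
#'
#' Bundles the eight payoff-difference parameters and the power of
#' population 1 into a `game_params` object, the complete specification of the
#' two-population replicator model. Lower-case `b`, `c` describe in-group
#' (same-population) interactions, upper-case `B`, `C` out-group interactions;
#' `B = S - P` is the gain from abandoning coordinated but non-preferred
#' behavior and `C = R - T` the gain from coordinating on one's preferred
#' behavior.
#'
#' The shorthand form `game_params(B, C, f)` sets `b1 = b2 = B1 = B2 = B` and
#' `c1 = c2 = C1 = C2 = C`, i.e. no difference between in-group and out-group
#' interactions; this is the convention used throughout the phase-diagram
#' sweeps.
#'
#' @param B,C shorthand payoff-difference parameters applied to both
#'   populations, in-group and out-group alike. Ignored when the full set is
#'   given.
#' @param f relative power of population 1, in `[0, 1]`; `1 - f` is the power
#'   of population 2.
#' @param b1,c1,b2,c2 in-group payoff differences per population.
#' @param B1,C1,B2,C2 out-group payoff differences per population.
#' @return An object of class `game_params`: a named list with components
#'   `b1, c1, b2, c2, B1, C1, B2, C2, f`.
#' @examples
#' g <- game_params(B = -1, C = -1, f = 0.8)   # two-population prisoner's dilemma
#' classify_game(g$b1, g$c1)
#' @export
game_params <- function(B = NULL, C = NULL, f = 0.5,
                        b1 = NULL, c1 = NULL, b2 = NULL, c2 = NULL,
                        B1 = NULL, C1 = NULL, B2 = NULL, C2 = NULL) {
  full <- list(b1 = b1, c1 = c1, b2 = b2, c2 = c2,
               B1 = B1, C1 = C1, B2 = B2, C2 = C2)
  if (all(vapply(full, is.null, logical(1)))) {
    if (is.null(B) || is.null(C))
      stop("supply either shorthand (B, C) or the full parameter set")
    full <- list(b1 = B, c1 = C, b2 = B, c2 = C,
                 B1 = B, C1 = C, B2 = B, C2 = C)
  } else if (any(vapply(full, is.null, logical(1)))) {
    stop("the full parameter set requires all of b1, c1, b2, c2, B1, C1, B2, C2")
  }
  vals <- c(unlist(full), f = f)
  if (!all(is.finite(vals))) stop("all game parameters must be finite")
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  structure(c(lapply(full, as.numeric), list(f = as.numeric(f))),
            class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat("Two-population game parameters (power f =", format(x$f), ")\n")
  cat(sprintf("  population 1: in-group (b, c) = (%g, %g)  out-group (B, C) = (%g, %g)  [%s / %s]\n",
              x$b1, x$c1, x$B1, x$C1,
              classify_game(x$b1, x$c1), classify_game(x$B1, x$C1)))
  cat(sprintf("  population 2: in-group (b, c) = (%g, %g)  out-group (B, C) = (%g, %g)  [%s / %s]\n",
              x$b2, x$c2, x$B2, x$C2,
              classify_game(x$b2, x$c2), classify_game(x$B2, x$C2)))
  invisible(x)
}

#' Payoff-difference parameters from a 2x2 payoff matrix
#'
#' Computes `B = S - P` and `C = R - T` from the four payoffs of a symmetric
#' 2x2 game: `R` (reward for mutual cooperation), `S` (sucker's payoff for
#' unilateral cooperation), `T` (temptation of unilateral defection) and `P`
#' (punishment for mutual defection).
#'
#' @param R,S,T,P the four payoffs (finite numerics).
#' @return Named numeric vector `c(B = S - P, C = R - T)`.
#' @examples
#' params_from_payoffs(R = 3, S = 0, T = 5, P = 1)  # B = -1, C = -2: a PD
#' @export
params_from_payoffs <- function(R, S, T, P) {
  R <- unname(R); S <- unname(S); T <- unname(T); P <- unname(P)
  v <- c(R = R, S = S, T = T, P = P)
  if (!all(is.finite(v))) stop("payoff entries must be finite")
  c(B = S - P, C = R - T)
}

#' Classify a symmetric 2x2 game from (B, C)
#'
#' The signs of `B = S - P` and `C = R - T` determine the character of the
#' game: both negative gives the prisoner's dilemma (`"PD"`, defection
#' dominant), `B > 0, C < 0` the snowdrift game (`"SD"`, stable coexistence),
#' `B < 0, C > 0` the stag hunt (`"SH"`, bistable with a threshold), and both
#' positive the harmony game (`"HG"`, cooperation dominant). A zero in either
#' coordinate (within `tol`) is reported as `"degenerate"`, never silently
#' binned into a named game.
#'
#' @param B,C payoff-difference parameters.
#' @param tol absolute tolerance below which a coordinate counts as zero.
#' @return One of `"PD"`, `"SD"`, `"SH"`, `"HG"`, `"degenerate"`.
#' @export
classify_game <- function(B, C, tol = 1e-12) {
  if (!is.finite(B) || !is.finite(C)) stop("B and C must be finite")
  if (abs(B) <= tol || abs(C) <= tol) return("degenerate")
  if (B < 0 && C < 0) "PD"
  else if (B > 0 && C < 0) "SD"
  else if (B < 0 && C > 0) "SH"
  else "HG"
}

#' Benefit/coordination parametrization
#'
#' Builds the payoff matrix from a benefit `b` of showing one's preferred
#' behavior and a benefit `c` of showing coordinated behavior. Two printed
#' variants exist: `"conformity"` (reward for conforming with the partner,
#' payoffs `P = c`, `R = b + c`, `S = b`, `T = 0`) and `"disapproval"` (mutual
#' disapproval of the non-preferred behavior, payoffs `P = 0`, `R = b`,
#' `S = b - c`, `T = -c`). Both yield identical difference parameters
#' `B = b - c`, `C = b + c`, hence identical dynamics — which is precisely why
#' the parametrization is useful.
#'
#' @param b benefit of showing the preferred behavior.
#' @param c benefit of showing coordinated behavior.
#' @param variant `"conformity"` or `"disapproval"`.
#' @return A list with components `payoffs` (named vector `R`, `S`, `T`, `P`),
#'   `B` and `C`.
#' @export
params_from_benefit_coordination <- function(b, c,
                                             variant = c("conformity", "disapproval")) {
  variant <- match.arg(variant)
  m <- switch(variant,
    conformity  = c(R = b + c, S = b,     T = 0,  P = c),
    disapproval = c(R = b,     S = b - c, T = -c, P = 0))
  bc <- params_from_payoffs(m["R"], m["S"], m["T"], m["P"])
  list(payoffs = m, B = unname(bc["B"]), C = unname(bc["C"]))
}

#' Costly punishment parameters
#'
#' A unilateral cooperator — an individual receiving the sucker's payoff `S`
#' from its own point of view — sanctions the defecting partner, subtracting a
#' fine `beta` from the partner's payoff at a cost `gamma` to itself.
#'
#' @param gamma punishment cost (both populations), or `gamma1`/`gamma2`.
#' @param beta punishment fine (both populations), or `beta1`/`beta2`.
#' @param gamma1,gamma2,beta1,beta2 per-population values; default to the
#'   shared `gamma`, `beta`.
#' @return An object of class `punishment_params`.
#' @export
punishment_params <- function(gamma = 0, beta = 0,
                              gamma1 = gamma, gamma2 = gamma,
                              beta1 = beta, beta2 = beta) {
  v <- c(gamma1 = gamma1, gamma2 = gamma2, beta1 = beta1, beta2 = beta2)
  if (!all(is.finite(v))) stop("punishment parameters must be finite")
  if (any(v < 0)) stop("punishment costs and fines must be nonnegative")
  if (beta1 < gamma1 || beta2 < gamma2)
    warning("fine below cost (beta < gamma); usually one assumes the fine exceeds the cost")
  structure(as.list(v), class = "punishment_params")
}

#' Apply the costly-punishment payoff transformation
#'
#' In-group: the cooperator receiving `S` pays the cost, so `b_a' = b_a -
#' gamma_a`; the defector's temptation is cut by the fine, so `c_a' = c_a +
#' beta_a`. For a prisoner's dilemma this turns the in-group game into a stag
#' hunt exactly when `beta_a > |c_a|`. Cross-population: in a discoordinated
#' encounter each side perceives itself as the unilateral cooperator, so with
#' `cross = "both"` (default) both punish and `B_a' = B_a - gamma_a -
#' beta_other`, leaving `C_a' = C_a` — the cross-group prisoner's dilemma
#' remains a prisoner's dilemma. `cross = "one_sided"` applies only the own
#' punishment cost (`B_a' = B_a - gamma_a`).
#'
#' @param g a [game_params] object.
#' @param pp a [punishment_params] object.
#' @param cross `"both"` (each side of a discoordinated cross encounter
#'   punishes) or `"one_sided"`.
#' @return A transformed `game_params` object; `f` is unchanged.
#' @examples
#' g <- game_params(B = -1, C = -2, f = 0.8)
#' apply_punishment(g, punishment_params(gamma = 2.5, beta = 12.5))
#' @export
apply_punishment <- function(g, pp, cross = c("both", "one_sided")) {
  cross <- match.arg(cross)
  stopifnot(inherits(g, "game_params"), inherits(pp, "punishment_params"))
  game_params(f = g$f,
              b1 = g$b1 - pp$gamma1, c1 = g$c1 + pp$beta1,
              b2 = g$b2 - pp$gamma2, c2 = g$c2 + pp$beta2,
              B1 = g$B1 - pp$gamma1 - if (cross == "both") pp$beta2 else 0,
              C1 = g$C1,
              B2 = g$B2 - pp$gamma2 - if (cross == "both") pp$beta1 else 0,
              C2 = g$C2)
}

#' Apply group pressure to a (B, C) pair
#'
#' Group pressure supporting conformity subtracts a value `g` from the
#' off-diagonal payoffs `S` and `T` (equivalently, adds `g` to the diagonal
#' payoffs `R` and `P`), yielding `B' = B - g` and `C' = C + g`. A prisoner's
#' dilemma is transformed into a stag hunt exactly when `g > |C|`.
#'
#' @param B,C payoff-difference parameters.
#' @param g group-pressure strength, `>= 0`.
#' @return Named numeric vector `c(B, C)` after the transformation.
#' @export
apply_group_pressure <- function(B, C, g) {
  if (!is.finite(g) || g < 0) stop("group pressure g must be a nonnegative number")
  c(B = B - g, C = C + g)
}

#' One-population replicator outcome
#'
#' For a single well-mixed population playing a symmetric 2x2 game, the
#' replicator dynamics outcome is determined by the game class and, for the
#' stag hunt, by the initial fraction of cooperators relative to the unstable
#' threshold `|B| / (|B| + |C|)`: prisoner's dilemma ends at 0, harmony at 1,
#' snowdrift at stable coexistence `|B| / (|B| + |C|)`, and the stag hunt at 1
#' or 0 according to whether `p0` is above or below the threshold (the
#' threshold itself is stationary).
#'
#' @param B,C payoff-difference parameters (non-degenerate).
#' @param p0 initial fraction of cooperators, in `[0, 1]`.
#' @return A list with `outcome` (final fraction) and, for SD/SH, `threshold`
#'   (`|B| / (|B| + |C|)`), plus the game `class`.
#' @export
predict_one_population <- function(B, C, p0) {
  cls <- classify_game(B, C)
  if (cls == "degenerate") stop("degenerate game: B or C is zero")
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  thr <- abs(B) / (abs(B) + abs(C))
  out <- switch(cls,
    PD = 0,
    HG = 1,
    SD = thr,
    SH = if (p0 > thr) 1 else if (p0 < thr) 0 else thr)
  list(outcome = out, threshold = if (cls %in% c("SD", "SH")) thr else NA_real_,
       class = cls)
}

#' In-group and out-group payoff matrices
#'
#' Constructs the four 2x2 payoff matrices of the model from a `game_params`
#' object, anchoring the payoff levels at `T = P = baseline` so that
#' `R = C + baseline` and `S = B + baseline`. Rows index the focal
#' individual's behavior and columns the partner's behavior, each in the
#' focal population's own labeling with the population's preferred
#' (cooperative) behavior first; the population-2 matrices are the mirrored
#' forms implied by the incompatible preferences, generated from its own
#' `(b2, c2, B2, C2)`.
#'
#' @param g a [game_params] object.
#' @param baseline payoff level assigned to `T` and `P` (differences are all
#'   that matter for the dynamics).
#' @return A list of four 2x2 matrices: `in1`, `out1`, `in2`, `out2`.
#' @export
payoff_matrices <- function(g, baseline = 0) {
  stopifnot(inherits(g, "game_params"))
  mk <- function(B, C) matrix(c(C + baseline, baseline,  # column 1: partner cooperates
                                B + baseline, baseline), # column 2: partner defects
                              nrow = 2,
                              dimnames = list(focal = c("coop", "defect"),
                                              partner = c("coop", "defect")))
  list(in1 = mk(g$b1, g$c1), out1 = mk(g$B1, g$C1),
       in2 = mk(g$b2, g$c2), out2 = mk(g$B2, g$C2))
}
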