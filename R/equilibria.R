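# Affine coefficients of the growth brackets:
#   G1 = a1 + u1 p + v1 q,  G2 = a2 + u2 p + v2 q
.bracket_coefs <- function(g) {
  f <- g$f
  list(a1 = f * g$b1 + (1 - f) * g$C1,
       u1 = f * (g$c1 - g$b1),
       v1 = (1 - f) * (g$B1 - g$C1),
       a2 = (1 - f) * g$b2 + f * g$C2,
       u2 = f * (g$B2 - g$C2),
       v2 = (1 - f) * (g$c2 - g$b2))
}

#' Jacobian of the replicator flow
#'
#' Closed-form linearization exploiting the affine structure of the growth
#' brackets: with `G1 = a1 + u1 p + v1 q`,
#' `d(dp/dt)/dp = (1 - 2p) G1 + p(1-p) u1`, `d(dp/dt)/dq = p(1-p) v1`, and
#' analogously for the second row.
#'
#' @param g a [game_params] object.
#' @param p,q evaluation point.
#' @return A 2x2 numeric matrix.
#' @export
replicator_jacobian <- function(g, p, q) {
  k <- .bracket_coefs(g)
  G <- growth_brackets(g, p, q)
  matrix(c((1 - 2 * p) * G$G1 + p * (1 - p) * k$u1,
           q * (1 - q) * k$u2,
           p * (1 - p) * k$v1,
           (1 - 2 * q) * G$G2 + q * (1 - q) * k$v2),
         nrow = 2)
}

#' Classify the stability of a fixed point from its Jacobian
#'
#' @param J 2x2 Jacobian matrix at the fixed point.
#' @param tol hyperbolicity tolerance on eigenvalue real parts; any real part
#'   within `tol` of zero makes the point `"nonhyperbolic"`.
#' @return A list with `stability` (one of `"stable"`, `"unstable"`,
#'   `"saddle"`, `"nonhyperbolic"`) and `eigenvalues` (complex vector).
#' @export
classify_stability <- function(J, tol = 1e-8) {
  if (!all(is.finite(J))) stop("Jacobian entries must be finite")
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  stability <-
    if (any(abs(re) <= tol)) "nonhyperbolic"
    else if (all(re < 0)) "stable"
    else if (all(re > 0)) "unstable"
    else "saddle"
  list(stability = stability, eigenvalues = as.complex(ev))
}

.make_fixed_point <- function(g, p, q, kind, tol_stab = 1e-8) {
  J <- replicator_jacobian(g, p, q)
  cls <- classify_stability(J, tol_stab)
  d <- replicator_rhs(g, p, q)
  list(p = p, q = q, kind = kind,
       eigenvalues = cls$eigenvalues, stability = cls$stability,
       residual = max(abs(c(d$dp, d$dq))))
}

# Clip the line a p + b q = c to the unit square; returns endpoints or NULL.
.clip_line_to_square <- function(a, b, c) {
  pts <- list()
  add <- function(p, q) {
    if (p >= -1e-12 && p <= 1 + 1e-12 && q >= -1e-12 && q <= 1 + 1e-12)
      pts[[length(pts) + 1]] <<- c(p = min(max(p, 0), 1), q = min(max(q, 0), 1))
  }
  if (abs(b) > 1e-14) { add(0, c / b); add(1, (c - a) / b) }
  if (abs(a) > 1e-14) { add(c / a, 0); add((c - b) / a, 1) }
  if (!length(pts)) return(NULL)
  m <- unique(round(do.call(rbind, pts), 12))
  if (nrow(m) < 2) return(NULL)
  # farthest pair
  dmax <- -1; best <- NULL
  for (i in seq_len(nrow(m) - 1)) for (j in seq(i + 1, nrow(m))) {
    dd <- sum((m[i, ] - m[j, ])^2)
    if (dd > dmax) { dmax <- dd; best <- m[c(i, j), ] }
  }
  if (dmax < 1e-16) return(NULL)
  best
}

#' Enumerate all stationary solutions of the two-population flow
#'
#' Uses the affine structure of the growth brackets to find every fixed point
#' analytically: the four corners; edge points where the relevant bracket's
#' affine restriction vanishes inside an edge; and the interior solution of
#' the 2x2 linear system `G1 = G2 = 0` — a unique point when the coefficient
#' determinant is nonzero and the solution lies in the open square, or an
#' equilibrium continuum (a line segment) when the two zero-sets coincide.
#' Coincidence is declared when, after normalizing each bracket's coefficient
#' vector to unit sup-norm, the 2x2 determinant and both augmented
#' determinants are below `det_tol` in magnitude.
#'
#' @param g a [game_params] object.
#' @param det_tol coincidence tolerance for continuum detection.
#' @param tol_stab hyperbolicity tolerance passed to [classify_stability()].
#' @return An object of class `equilibrium_set`: list with `points` (list of
#'   fixed points, each with `p`, `q`, `kind`, `eigenvalues`, `stability`,
#'   `residual`) and `continuum` (either `NULL` or a list with the line
#'   coefficients `a`, `b`, `c` of `a p + b q = c` and its `endpoints` in the
#'   unit square).
#' @examples
#' eq <- enumerate_fixed_points(game_params(B = -1, C = 1, f = 0.8))
#' eq$continuum$line   # the C = -B equilibrium line
#' @export
enumerate_fixed_points <- function(g, det_tol = 1e-10, tol_stab = 1e-8) {
  stopifnot(inherits(g, "game_params"))
  k <- .bracket_coefs(g)
  pts <- list()
  add <- function(p, q, kind) {
    for (ex in pts)
      if (abs(ex$p - p) < 1e-8 && abs(ex$q - q) < 1e-8) return(invisible())
    pts[[length(pts) + 1]] <<- .make_fixed_point(g, p, q, kind, tol_stab)
  }
  for (p in c(0, 1)) for (q in c(0, 1)) add(p, q, "corner")

  in_open <- function(x) x > 1e-10 && x < 1 - 1e-10
  # q = 0 and q = 1 edges: G1(p, q_e) = 0
  for (qe in c(0, 1)) {
    if (abs(k$u1) > 1e-14) {
      p <- -(k$a1 + k$v1 * qe) / k$u1
      if (in_open(p)) add(p, qe, "edge")
    }
  }
  # p = 0 and p = 1 edges: G2(p_e, q) = 0
  for (pe in c(0, 1)) {
    if (abs(k$v2) > 1e-14) {
      q <- -(k$a2 + k$u2 * pe) / k$v2
      if (in_open(q)) add(pe, q, "edge")
    }
  }

  continuum <- NULL
  r1 <- c(k$u1, k$v1, -k$a1)
  r2 <- c(k$u2, k$v2, -k$a2)
  n1 <- max(abs(r1)); n2 <- max(abs(r2))
  if (n1 < 1e-14 && n2 < 1e-14) {
    warning("both growth brackets vanish identically; every state is stationary")
  } else if (n1 < 1e-14 || n2 < 1e-14) {
    # one bracket identically zero: the other's zero line is a continuum
    r <- if (n1 < 1e-14) r2 / n2 else r1 / n1
    ep <- .clip_line_to_square(r[1], r[2], r[3])
    if (!is.null(ep))
      continuum <- list(line = c(a = r[1], b = r[2], c = r[3]), endpoints = ep)
  } else {
    s1 <- r1 / n1; s2 <- r2 / n2
    det12 <- s1[1] * s2[2] - s2[1] * s1[2]
    aug1  <- s1[1] * s2[3] - s2[1] * s1[3]
    aug2  <- s1[2] * s2[3] - s2[2] * s1[3]
    if (abs(det12) < det_tol && abs(aug1) < det_tol && abs(aug2) < det_tol) {
      ep <- .clip_line_to_square(s1[1], s1[2], s1[3])
      if (!is.null(ep))
        continuum <- list(line = c(a = s1[1], b = s1[2], c = s1[3]),
                          endpoints = ep)
    } else if (abs(det12) >= det_tol) {
      det <- k$u1 * k$v2 - k$u2 * k$v1
      p <- (-k$a1 * k$v2 + k$a2 * k$v1) / det
      q <- (-k$a2 * k$u1 + k$a1 * k$u2) / det
      if (in_open(p) && in_open(q)) add(p, q, "interior")
    }
  }
  structure(list(points = pts, continuum = continuum, params = g),
            class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat("Equilibrium set:", length(x$points), "isolated fixed point(s)\n")
  for (fp in x$points)
    cat(sprintf("  (%.6f, %.6f)  %-8s %s\n", fp$p, fp$q, fp$kind, fp$stability))
  if (!is.null(x$continuum))
    cat(sprintf("  continuum line: %.4f p + %.4f q = %.4f\n",
                x$continuum$line["a"], x$continuum$line["b"],
                x$continuum$line["c"]))
  invisible(x)
}

#' Nash-equilibrium check at a fixed point
#'
#' Verifies that at the state `(p, q)` no unilateral switch to a pure behavior
#' by a representative individual of either population increases its expected
#' payoff (within `tol`). Every asymptotically or neutrally stable fixed point
#' of the replicator flow should pass; unstable fixed points need not.
#'
#' @param g a [game_params] object.
#' @param p,q the state to check.
#' @param tol payoff-improvement tolerance.
#' @return A list with `nash` (logical) and the per-population payoff
#'   advantages `G1`, `G2` of the preferred behavior at `(p, q)`.
#' @export
nash_check <- function(g, p, q, tol = 1e-9) {
  G <- growth_brackets(g, p, q)
  ok1 <- if (p > tol && p < 1 - tol) abs(G$G1) <= tol
         else if (p >= 1 - tol) G$G1 >= -tol else G$G1 <= tol
  ok2 <- if (q > tol && q < 1 - tol) abs(G$G2) <= tol
         else if (q >= 1 - tol) G$G2 >= -tol else G$G2 <= tol
  list(nash = ok1 && ok2, G1 = G$G1, G2 = G$G2)
}

#' JSON report of an equilibrium set
#'
#' @param eq an `equilibrium_set`.
#' @param path output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
equilibria_json <- function(eq, path = NULL) {
  stopifnot(inherits(eq, "equilibrium_set"))
  rep <- list(
    fixed_points = lapply(eq$points, function(fp)
      list(p = fp$p, q = fp$q, kind = fp$kind,
           eigenvalues = list(re = Re(fp$eigenvalues), im = Im(fp$eigenvalues)),
           stability = fp$stability)),
    continuum = if (is.null(eq$continuum)) NULL else
      list(a = unname(eq$continuum$line["a"]),
           b = unname(eq$continuum$line["b"]),
           c = unname(eq$continuum$line["c"]),
           endpoints = apply(eq$continuum$endpoints, 1, as.list)))
  if (is.null(path)) {
    jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}
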