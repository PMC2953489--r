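# Shorthand constructor used throughout the suite.
sh <- function(B, C, f) game_params(B = B, C = C, f = f)

# Random non-degenerate shorthand draw (caller sets the seed).
random_shorthand <- function() {
  repeat {
    B <- runif(1, -2, 2); C <- runif(1, -2, 2)
    if (abs(B) > 0.05 && abs(C) > 0.05) break
  }
  sh(B, C, runif(1, 0.05, 0.95))
}

# Random full (eight-parameter) draw.
random_full <- function() {
  v <- runif(8, -2, 2)
  game_params(f = runif(1, 0.05, 0.95),
              b1 = v[1], c1 = v[2], b2 = v[3], c2 = v[4],
              B1 = v[5], C1 = v[6], B2 = v[7], C2 = v[8])
}

# Brute-force check helper: rhs sup-norm on an n x n grid; every local
# minimum below `thresh` must lie near a returned point or the continuum.
grid_scan_agrees <- function(g, eq, n = 200, thresh = 1e-3, match = 1e-2) {
  lat <- seq(0, 1, length.out = n)
  P <- matrix(lat, n, n); Q <- matrix(lat, n, n, byrow = TRUE)
  d <- replicator_rhs(g, P, Q)
  nm <- pmax(abs(d$dp), abs(d$dq))
  ok <- TRUE
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (nm[i, j] >= thresh) next
    ni <- max(1, i - 1):min(n, i + 1); nj <- max(1, j - 1):min(n, j + 1)
    if (nm[i, j] > min(nm[ni, nj])) next  # not a local minimum
    p <- lat[i]; q <- lat[j]
    dists <- vapply(eq$points,
                    function(fp) sqrt((fp$p - p)^2 + (fp$q - q)^2), 0)
    dc <- normdyn:::.continuum_distance(eq$continuum, p, q)
    if (min(c(dists, dc)) > match) ok <- FALSE
  }
  ok
}

# Normalize a line coefficient vector (a, b, c) of a p + b q = c to unit
# sup-norm with a sign convention, so lines compare regardless of scaling.
norm_line <- function(v) {
  v <- unname(v) / max(abs(v))
  i <- which(abs(v) > 1e-12)[1]
  v * sign(v[i])
}
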