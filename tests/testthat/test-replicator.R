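test_that("growth brackets collapse to constants when b = c", {
  g <- sh(-1, -1, 0.8)
  set.seed(1)
  for (i in 1:10) {
    s <- runif(2)
    G <- growth_brackets(g, s[1], s[2])
    expect_equal(G$G1, -1); expect_equal(G$G2, -1)
  }
})

test_that("C = -B shorthand makes G2 = -G1 at every state", {
  set.seed(2)
  for (i in 1:10) {
    B <- runif(1, -2, 2); f <- runif(1, 0.05, 0.95)
    g <- sh(B, -B, f)
    s <- matrix(runif(20), ncol = 2)
    G <- growth_brackets(g, s[, 1], s[, 2])
    expect_equal(G$G2, -G$G1)
  }
})

test_that("brackets equal the expected-payoff difference between behaviors", {
  set.seed(3)
  for (i in 1:15) {
    g <- random_full()
    p <- runif(1); q <- runif(1)
    G <- growth_brackets(g, p, q)
    expect_equal(G$G1, expected_payoff(g, 1, 1, p, q) -
                       expected_payoff(g, 1, 2, p, q))
    expect_equal(G$G2, expected_payoff(g, 2, 2, p, q) -
                       expected_payoff(g, 2, 1, p, q))
  }
})

test_that("edges and corners of the unit square are invariant", {
  set.seed(4)
  for (i in 1:10) {
    g <- random_full()
    q <- runif(1)
    expect_equal(replicator_rhs(g, 0, q)$dp, 0)
    expect_equal(replicator_rhs(g, 1, q)$dp, 0)
    expect_equal(replicator_rhs(g, q, 0)$dq, 0)
    expect_equal(replicator_rhs(g, q, 1)$dq, 0)
    d <- replicator_rhs(g, 1, 1)
    expect_equal(c(d$dp, d$dq), c(0, 0))
  }
})

test_that("integration matches the logistic closed form of the shorthand PD", {
  # B = C = -1 gives dp/dt = -p(1-p): p(t) = p0 e^-t / (1 - p0 + p0 e^-t),
  # so p(ln 9) = 0.1 from p0 = 0.5
  g <- sh(-1, -1, 0.8)
  tr <- integrate_replicator(g, 0.5, 0.5, t_end = log(9), n_out = 2,
                             eps_conv = 0)
  p_end <- tr$states[nrow(tr$states), "p"]
  expect_equal(unname(p_end), 0.1, tolerance = 1e-6)
})

test_that("find_attractor reaches the published fixed points", {
  expect_equal(find_attractor(sh(1, 1, 0.8), 0.1, 0.1)$attractor,
               c(p = 1, q = 1), tolerance = 1e-6)
  fa <- find_attractor(sh(1, -2, 0.8), 0.5, 0.5)
  expect_true(fa$converged)
  expect_equal(fa$attractor, c(p = 1 / 6, q = 0), tolerance = 1e-6)
  # diagonal-invariant stag hunt with f = 1/2 climbs to (1, 1)
  fa2 <- find_attractor(sh(-1, 2, 0.5), 0.5, 0.5)
  expect_equal(fa2$attractor, c(p = 1, q = 1), tolerance = 1e-6)
})

test_that("a start on a fixed point stays there", {
  g <- sh(-1, 1, 0.8)  # (1, 1) is a saddle, but exactly stationary
  fa <- find_attractor(g, 1, 1)
  expect_true(fa$converged)
  expect_equal(fa$attractor, c(p = 1, q = 1))
  # interior threshold point of the one-population stag hunt limit
  g1 <- game_params(f = 0.5, b1 = -1, c1 = 2, b2 = -1, c2 = 2,
                    B1 = 0, C1 = 0, B2 = 0, C2 = 0)
  fa2 <- find_attractor(g1, 1 / 3, 1 / 3)
  expect_true(fa2$converged)
  expect_equal(fa2$attractor, c(p = 1 / 3, q = 1 / 3), tolerance = 1e-9)
})

test_that("rescaling all payoff parameters preserves attractors", {
  set.seed(6)
  for (i in 1:5) {
    g <- random_full()
    lam <- runif(1, 0.2, 5)
    gs <- game_params(f = g$f,
                      b1 = lam * g$b1, c1 = lam * g$c1,
                      b2 = lam * g$b2, c2 = lam * g$c2,
                      B1 = lam * g$B1, C1 = lam * g$C1,
                      B2 = lam * g$B2, C2 = lam * g$C2)
    a <- find_attractor(g, 0.3, 0.7)
    b <- find_attractor(gs, 0.3, 0.7)
    if (a$converged && b$converged)
      expect_equal(a$attractor, b$attractor, tolerance = 1e-5)
  }
})

test_that("with out-group parameters zero the populations decouple", {
  # each (B, C) quadrant reproduces the one-population outcome
  quadrants <- list(PD = c(-1, -2), HG = c(1, 2), SD = c(1, -2), SH = c(-1, 2))
  for (nm in names(quadrants)) {
    bc <- quadrants[[nm]]
    g <- game_params(f = 0.8, b1 = bc[1], c1 = bc[2], b2 = bc[1], c2 = bc[2],
                     B1 = 0, C1 = 0, B2 = 0, C2 = 0)
    p0 <- 0.6; q0 <- 0.25
    fa <- find_attractor(g, p0, q0)
    expect_true(fa$converged)
    expect_equal(unname(fa$attractor["p"]),
                 predict_one_population(bc[1], bc[2], p0)$outcome,
                 tolerance = 1e-6)
    expect_equal(unname(fa$attractor["q"]),
                 predict_one_population(bc[1], bc[2], q0)$outcome,
                 tolerance = 1e-6)
  }
})

test_that("with in-group parameters zero each bracket sees only the other population", {
  g <- game_params(f = 0.7, b1 = 0, c1 = 0, b2 = 0, c2 = 0,
                   B1 = -1, C1 = 2, B2 = -1, C2 = 2)
  set.seed(8)
  q <- runif(1)
  G_p0 <- growth_brackets(g, 0.1, q)
  G_p1 <- growth_brackets(g, 0.9, q)
  expect_equal(G_p0$G1, G_p1$G1)          # G1 independent of p
  p <- runif(1)
  G_q0 <- growth_brackets(g, p, 0.1)
  G_q1 <- growth_brackets(g, p, 0.9)
  expect_equal(G_q0$G2, G_q1$G2)          # G2 independent of q
})

test_that("trajectory output is monotone in time and inside the unit square", {
  g <- sh(-1, 2, 0.8)
  tr <- integrate_replicator(g, 0.9, 0.1, t_end = 50)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$states >= 0 & tr$states <= 1))
  tmp_csv <- tempfile(fileext = ".csv"); tmp_json <- tempfile(fileext = ".json")
  write_trajectory(tr, csv = tmp_csv, json = tmp_json)
  back <- read.csv(tmp_csv)
  expect_equal(back$p, unname(tr$states[, "p"]))
  js <- jsonlite::read_json(tmp_json)
  expect_identical(js$converged, tr$converged)
})
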