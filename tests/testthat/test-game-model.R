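test_that("B and C are the payoff differences S - P and R - T", {
  expect_equal(params_from_payoffs(R = 3, S = 0, T = 5, P = 1),
               c(B = -1, C = -2))
  expect_equal(params_from_payoffs(0, 0, 0, 0), c(B = 0, C = 0))
  # benefit/coordination payoffs P = c, R = b + c, S = b, T = 0
  b <- 1.3; c <- 0.4
  expect_equal(params_from_payoffs(R = b + c, S = b, T = 0, P = c),
               c(B = b - c, C = b + c))
  expect_error(params_from_payoffs(Inf, 0, 0, 0), "finite")
})

test_that("params_from_payoffs is invariant under a common payoff shift", {
  set.seed(11)
  for (i in 1:20) {
    v <- runif(4, -5, 5); k <- runif(1, -10, 10)
    expect_equal(params_from_payoffs(v[1], v[2], v[3], v[4]),
                 params_from_payoffs(v[1] + k, v[2] + k, v[3] + k, v[4] + k))
  }
})

test_that("sign quadrants of (B, C) select the four game classes", {
  expect_identical(classify_game(-1, -1), "PD")
  expect_identical(classify_game(1, 1), "HG")
  expect_identical(classify_game(1, -1), "SD")
  expect_identical(classify_game(-1, 1), "SH")
  expect_identical(classify_game(0, 5), "degenerate")
  expect_identical(classify_game(2, 1e-13), "degenerate")
})

test_that("conformity and disapproval parametrizations agree on (B, C)", {
  a <- params_from_benefit_coordination(1, 2, "conformity")
  b <- params_from_benefit_coordination(1, 2, "disapproval")
  expect_equal(a$B, -1); expect_equal(a$C, 3)
  expect_equal(b$B, a$B); expect_equal(b$C, a$C)
  expect_false(isTRUE(all.equal(a$payoffs, b$payoffs)))  # matrices differ
  set.seed(7)
  for (i in 1:25) {
    bb <- runif(1, -3, 3); cc <- runif(1, -3, 3)
    x <- params_from_benefit_coordination(bb, cc, "conformity")
    y <- params_from_benefit_coordination(bb, cc, "disapproval")
    expect_equal(c(x$B, x$C), c(y$B, y$C))
    expect_equal(c(x$B, x$C), c(bb - cc, bb + cc))
  }
  z <- params_from_benefit_coordination(0, 0)
  expect_equal(c(z$B, z$C), c(0, 0))
})

test_that("costly punishment shifts in-group to stag hunt, cross stays PD", {
  g <- sh(-1, -2, 0.8)
  pp <- punishment_params(gamma = 2.5, beta = 12.5)
  gp <- apply_punishment(g, pp)
  expect_equal(gp$b1, -3.5); expect_equal(gp$c1, 10.5)
  expect_equal(gp$B1, -16); expect_equal(gp$C1, -2)
  expect_identical(classify_game(gp$b1, gp$c1), "SH")
  expect_identical(classify_game(gp$B1, gp$C1), "PD")
  expect_equal(gp$f, g$f)
  # one-sided cross rule only subtracts the own punishment cost
  g1 <- apply_punishment(g, pp, cross = "one_sided")
  expect_equal(g1$B1, -1 - 2.5)
  expect_equal(g1$b1, gp$b1)

  # zero punishment is the identity
  expect_equal(unclass(apply_punishment(g, punishment_params(0, 0))),
               unclass(g))
  # beta = |c| lands exactly on the degenerate boundary
  gb <- apply_punishment(g, suppressWarnings(
    punishment_params(gamma = 2.5, beta = 2)))
  expect_equal(gb$c1, 0)
  expect_identical(classify_game(gb$b1, gb$c1), "degenerate")
})

test_that("punishment turns in-group PD into SH exactly when beta > |c|", {
  set.seed(21)
  for (i in 1:20) {
    b <- -runif(1, 0.1, 2); c <- -runif(1, 0.1, 2)
    g <- sh(b, c, 0.5)
    beta <- runif(1, 0, 4); gamma <- runif(1, 0, beta + 0.5)
    gp <- suppressWarnings(
      apply_punishment(g, punishment_params(gamma = gamma, beta = beta)))
    cls <- classify_game(gp$b1, gp$c1)
    if (abs(beta - abs(c)) > 1e-9)
      expect_identical(cls, if (beta > abs(c)) "SH" else "PD")
    # out-group: B decreases, C untouched, PD signs preserved
    expect_lte(gp$B1, g$B1)
    expect_equal(gp$C1, g$C1)
    expect_identical(classify_game(gp$B1, gp$C1), "PD")
  }
})

test_that("group pressure shifts (B, C) by (-g, +g) and PD -> SH at g > |C|", {
  expect_equal(apply_group_pressure(-1, -2, 3), c(B = -4, C = 1))
  expect_identical(do.call(classify_game,
                           as.list(unname(apply_group_pressure(-1, -2, 3)))),
                   "SH")
  expect_equal(apply_group_pressure(-1, -2, 0), c(B = -1, C = -2))
  expect_equal(apply_group_pressure(-1, -2, 2), c(B = -3, C = 0))
  expect_error(apply_group_pressure(-1, -2, -1), "nonnegative")
  set.seed(31)
  for (i in 1:15) {
    B <- -runif(1, 0.1, 2); C <- -runif(1, 0.1, 2); g <- runif(1, 0, 4)
    out <- apply_group_pressure(B, C, g)
    if (abs(g - abs(C)) > 1e-9)
      expect_identical(classify_game(out["B"], out["C"]),
                       if (g > abs(C)) "SH" else "PD")
  }
})

test_that("one-population outcomes follow the |B|/(|B|+|C|) rule", {
  expect_equal(predict_one_population(1, -1, 0.5)$outcome, 0.5)  # SD coexistence
  expect_equal(predict_one_population(-1, -5, 0.9)$outcome, 0)   # PD
  expect_equal(predict_one_population(2, 3, 0.1)$outcome, 1)     # HG
  # SH: threshold |B|/(|B|+|C|) = 1/3 separates the basins
  expect_equal(predict_one_population(-1, 2, 0.5)$outcome, 1)
  expect_equal(predict_one_population(-1, 2, 0.2)$outcome, 0)
  expect_equal(predict_one_population(-1, 2, 1 / 3)$outcome, 1 / 3)
  expect_error(predict_one_population(0, 1, 0.5), "degenerate")
})

test_that("shorthand and full constructors agree; invalid input rejected", {
  g <- sh(-1, 2, 0.7)
  gf <- game_params(f = 0.7, b1 = -1, c1 = 2, b2 = -1, c2 = 2,
                    B1 = -1, C1 = 2, B2 = -1, C2 = 2)
  expect_equal(unclass(g), unclass(gf))
  expect_error(game_params(B = 1, C = 1, f = 1.2), "f must lie")
  expect_error(game_params(B = NaN, C = 1, f = 0.5), "finite")
  expect_error(game_params(f = 0.5, b1 = 1), "full parameter set")
})

test_that("payoff matrices carry the right differences in both frames", {
  set.seed(5)
  g <- random_full()
  m <- payoff_matrices(g)
  expect_equal(m$in1["coop", "defect"] - m$in1["defect", "defect"], g$b1)
  expect_equal(m$in1["coop", "coop"] - m$in1["defect", "coop"], g$c1)
  expect_equal(m$out2["coop", "defect"] - m$out2["defect", "defect"], g$B2)
  expect_equal(m$in2["coop", "coop"] - m$in2["defect", "coop"], g$c2)
})
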