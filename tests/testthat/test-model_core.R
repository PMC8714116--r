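test_that("nondimensionalization reproduces the published scaled rates", {
  rates <- rate_constants()  # literature turnover values
  p <- nondimensionalize(rates)
  expect_equal(p$lam_W_SP, 1)
  expect_equal(p$lam_M_SP, 1)
  expect_equal(p$lam_W_PF, 100)
  expect_equal(p$lam_M_PF, 0.5)
  # lam_agg = k_agg * K_total / k_minus: 1e4 M^-1 s^-1 * 1e-3 M / 1e-3 s^-1
  p2 <- nondimensionalize(rate_constants(k_agg = 1e4, K_total = 1e-3,
                                         k_minus = 1e-3))
  expect_equal(p2$lam_agg, 1e4)
  # identity scaling: any rate equal to k_minus maps to 1
  p3 <- nondimensionalize(rate_constants(k_W_PF = 1e-3))
  expect_equal(p3$lam_W_PF, 1)
  expect_equal(p3$gamma, 10)  # passed through unchanged
})

test_that("non-positive rate constants are rejected by name", {
  expect_error(rate_constants(k_W_SP = 0), "k_W_SP")
  expect_error(rate_constants(gamma = -1), "gamma")
  expect_error(rate_constants(K_total = NA), "K_total")
  expect_error(model_params(lam_agg = 0), "lam_agg")
})

test_that("vector field matches the reaction scheme on simple states", {
  p <- default_params()
  expect_equal(unname(keratin_rhs(rep(0, 8), p)), rep(0, 8))
  # single active reaction: all keratin soluble wild-type, lam_W_SP = 1
  p1 <- model_params(lam_W_SP = 1, lam_M_SP = 1, lam_W_PF = 100,
                     lam_M_PF = 0.5, lam_agg = 1e4, gamma = 10)
  d <- keratin_rhs(initial_state(0), p1)
  expect_equal(unname(d["s_W"]), -1)
  expect_equal(unname(d["p_W"]), 1)
  expect_equal(unname(d[c("s_M", "p_M", "f_W", "f_M", "a_W", "a_M")]),
               rep(0, 6))
})

test_that("wild-type and mutant totals are conserved by construction", {
  set.seed(42)
  for (i in 1:50) {
    p <- random_params()
    d <- keratin_rhs(random_state(), p)
    wt <- d["s_W"] + d["p_W"] + d["f_W"] + d["a_W"]
    mu <- d["s_M"] + d["p_M"] + d["f_M"] + d["a_M"]
    # zero up to cancellation error in the largest flux term
    tol <- 1e-13 * max(1, max(abs(d)))
    expect_lt(abs(wt), tol)
    expect_lt(abs(mu), tol)
  }
})

test_that("invalid states are rejected", {
  p <- default_params()
  expect_error(keratin_rhs(c(-0.1, rep(0.1, 7)), p), "invalid state")
  expect_error(keratin_rhs(c(NaN, rep(0.1, 7)), p), "invalid state")
  expect_error(keratin_state(rep(0.1, 7)), "8 components")
})

test_that("initial_state allocates the requested mutant fraction", {
  s <- initial_state(0.25)
  expect_equal(unname(s["s_W"]), 0.75)
  expect_equal(unname(s["s_M"]), 0.25)
  expect_equal(sum(s), 1)
  expect_equal(chi_M_of(s), 0.25)

  s0 <- initial_state(0)
  expect_equal(unname(s0["s_W"]), 1)
  expect_equal(sum(s0[-1]), 0)

  su <- initial_state(0.5, "uniform")
  expect_equal(unname(su), rep(0.125, 8))
  expect_equal(chi_M_of(su), 0.5)

  expect_error(initial_state(1.2), "\\[0, 1\\]")
  expect_error(initial_state(-0.1), "\\[0, 1\\]")
})

test_that("chi_M and Q summaries follow their definitions", {
  expect_equal(chi_M_of(initial_state(0)), 0)
  expect_equal(chi_M_of(initial_state(1)), 1)
  st <- keratin_state(c(0, 0, 0.1, 0.1, 0.2, 0.2, 0.1, 0.1))
  expect_equal(Q_of(st), 1.0)
  # filament-free states are degenerate, not infinite
  expect_error(Q_of(keratin_state(c(0.5, 0.5, 0, 0, 0, 0, 0, 0))),
               "degenerate")
})

test_that("single-species steady-state Q equals 1/lam_PF at the endpoints", {
  p <- default_params()
  expect_equal(solve_algebraic(p, 0)$Q, 1 / p$lam_W_PF)
  expect_equal(solve_algebraic(p, 1)$Q, 1 / p$lam_M_PF)
})

test_that("scaled system is an exact reparametrization of the dimensional one", {
  rates <- rate_constants(gamma = 10, k_agg = 1e4)
  p <- nondimensionalize(rates)
  K <- rates$K_total
  y0_frac <- as.numeric(initial_state(0.3))
  tau_end <- 50
  times_tau <- seq(0, tau_end, length.out = 21)

  nd <- deSolve::lsoda(y0_frac, times_tau,
                       function(t, y, pr) list(kerataggr::keratin_rhs(pmax(y, 0), pr)),
                       p, rtol = 1e-12, atol = 1e-14)
  dm <- deSolve::lsoda(y0_frac * K, times_tau / rates$k_minus,
                       function(t, y, pr) {
                         list(kerataggr::keratin_rhs_dimensional(pmax(y, 0), pr))
                       },
                       rates, rtol = 1e-12, atol = 1e-14 * K)
  rescaled <- dm[, -1] / K
  expect_lt(max(rel_diff(rescaled[nrow(dm), ], nd[nrow(nd), -1])), 1e-8)
  expect_lt(max(abs(rescaled - nd[, -1])), 1e-8)
})
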