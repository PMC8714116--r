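test_that("pure wild-type and pure mutant steady states match closed forms", {
  p <- default_params()
  wt <- closed_form_wt(1, 100)   # s_W = 0.5, p_W = 1/202, f_W = 100/202
  mu <- closed_form_wt(1, 0.5)   # s_M = 0.5, p_M = 1/3,  f_M = 1/6

  for (solve in list(function(ch) integrate_to_stationary(p, initial_state(ch)),
                     function(ch) solve_algebraic(p, ch))) {
    ss0 <- solve(0)
    expect_true(ss0$converged)
    expect_equal(unname(ss0$state[c("s_W", "p_W", "f_W")]),
                 unname(wt), tolerance = 1e-6)
    expect_equal(sum(ss0$state[c("s_M", "p_M", "f_M", "a_W", "a_M")]), 0)

    ss1 <- solve(1)
    expect_equal(unname(ss1$state[c("s_M", "p_M", "f_M")]),
                 unname(mu), tolerance = 1e-6)
    expect_equal(sum(ss1$state[c("s_W", "p_W", "f_W", "a_W", "a_M")]), 0)
  }
})

test_that("both solvers reproduce the pinned interior fixture", {
  p <- default_params(gamma = 10, lam_agg = 1e4)
  alg <- solve_algebraic(p, 0.25)
  expect_lt(max(rel_diff(alg$state, oracle_state_g10_l1e4_chi025)), 1e-12)
  expect_equal(alg$Q, oracle_Q_g10_l1e4_chi025, tolerance = 1e-12)

  ss <- integrate_to_stationary(p, initial_state(0.25))
  expect_true(ss$converged)
  expect_lt(ss$max_abs_derivative, 1e-10)
  expect_lt(max(rel_diff(ss$state, oracle_state_g10_l1e4_chi025)), 1e-6)
  # the fixed point satisfies the vector field
  expect_lt(max(abs(keratin_rhs(alg$state, p))), 1e-9)
})

test_that("algebraic special cases decouple as expected", {
  # chi_M = 0: the mutant equation drops out, p_W is linear
  p <- default_params(gamma = 7, lam_agg = 123)
  a0 <- solve_algebraic(p, 0)
  expect_equal(unname(a0$state["p_W"]),
               1 / ((1 + 1 / p$lam_W_SP) * (1 + p$lam_W_PF)))
  expect_equal(unname(a0$state["p_M"]), 0)
  # symmetric species at gamma = 1 and chi_M = 0.5 give p_W = p_M
  psym <- model_params(lam_W_SP = 1, lam_M_SP = 1, lam_W_PF = 2,
                       lam_M_PF = 2, lam_agg = 50, gamma = 1)
  as <- solve_algebraic(psym, 0.5)
  expect_equal(unname(as$state["p_W"]), unname(as$state["p_M"]),
               tolerance = 1e-12)
})

test_that("integration and the algebraic oracle agree over random draws", {
  # the stopping residual bounds the distance to the fixed point along the
  # slow modes, so field-level agreement at rel. 1e-5 needs a stationarity
  # threshold well below the headline 1e-10 s^-1
  set.seed(7)
  for (i in 1:25) {
    p <- random_params()
    chi <- stats::runif(1, 0.01, 0.99)
    alg <- solve_algebraic(p, chi)
    ss <- integrate_to_stationary(p, initial_state(chi), threshold = 1e-13)
    expect_true(ss$converged)
    expect_lt(max(rel_diff(ss$state, alg$state)), 1e-5)
  }
})

test_that("trajectories preserve positivity and conserve chi_M", {
  p <- default_params(gamma = 20, lam_agg = 1e5)
  init <- initial_state(0.4)
  deriv <- function(t, y, pr) list(kerataggr::keratin_rhs(pmax(y, 0), pr))
  out <- deSolve::lsoda(as.numeric(init), seq(0, 500, by = 5), deriv, p,
                        rtol = 1e-10, atol = 1e-12)
  expect_gt(min(out[, -1]), -1e-12)
  chi_traj <- rowSums(out[, c(3, 5, 7, 9)])  # s_M, p_M, f_M, a_M columns
  expect_lt(max(abs(chi_traj - 0.4)), 1e-9)

  ss <- integrate_to_stationary(p, init)
  expect_lt(abs(ss$chi_M - 0.4), 1e-8)
})

test_that("vanishing aggregation rate leaves no aggregates at equilibrium", {
  p <- default_params(gamma = 5, lam_agg = 1e-12)
  ss <- integrate_to_stationary(p, initial_state(0.5))
  expect_lt(unname(ss$state["a_W"]), 1e-9)
  expect_lt(unname(ss$state["a_M"]), 1e-9)
  alg <- solve_algebraic(p, 0.5)
  expect_lt(unname(alg$state["a_W"] + alg$state["a_M"]), 1e-9)
})

test_that("the steady state does not depend on the initial allocation", {
  p <- default_params(gamma = 10, lam_agg = 1e4)
  for (chi in c(0.1, 0.25, 0.7)) {
    a <- integrate_to_stationary(p, initial_state(chi, "all_soluble"))
    b <- integrate_to_stationary(p, initial_state(chi, "uniform"))
    expect_true(a$converged && b$converged)
    expect_lt(max(rel_diff(a$state, b$state)), 1e-6)
  }
})

test_that("hitting tau_max reports non-convergence instead of truncating", {
  p <- default_params()
  ss <- integrate_to_stationary(p, initial_state(0.25), tau_max = 1,
                                check_dtau = 0.5)
  expect_false(ss$converged)
  expect_gte(ss$max_abs_derivative, 1e-10)
})

test_that("solver inputs are validated", {
  p <- default_params()
  expect_error(solve_algebraic(p, 1.5), "\\[0, 1\\]")
  expect_error(solve_algebraic(p, -0.1), "\\[0, 1\\]")
  expect_error(integrate_to_stationary(p, c(-1, rep(0.1, 7))), "invalid state")
})
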