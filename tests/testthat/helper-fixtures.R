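# Shared fixtures and small utilities for the suite.

default_params <- function(gamma = 10, lam_agg = 1e4) {
  model_params(lam_W_SP = 1, lam_M_SP = 1, lam_W_PF = 100, lam_M_PF = 0.5,
               lam_agg = lam_agg, gamma = gamma)
}

rel_diff <- function(a, b) {
  abs(a - b) / pmax(abs(b), .Machine$double.eps)
}

# Pinned regression fixture: steady state at gamma = 10, lam_agg = 1e4,
# chi_M = 0.25 with the default turnover rates.  Values were computed with
# the algebraic reduction (bracketed root-finding on the stationarity
# conditions) and are frozen here to 17 significant digits; the integrator
# reproduces them to ~1e-14 relative.
oracle_state_g10_l1e4_chi025 <- c(
  s_W = 0.375,
  s_M = 0.125,
  p_W = 6.2744897889869993e-05,
  p_M = 0.058755815645791791,
  f_W = 0.0062744897889869993,
  f_M = 0.029377907822895896,
  a_W = 0.36866276531312314,
  a_M = 0.036866276531312317
)
oracle_Q_g10_l1e4_chi025 <- 13.024302248703485

# Closed-form single-species steady states (chi_M = 0 and 1): with
# s = (p + f + a) / lam_SP, f = lam_PF * p, a = 0 and conservation,
# p = total / ((1 + 1/lam_SP) * (1 + lam_PF)).
closed_form_wt <- function(lam_SP = 1, lam_PF = 100) {
  p <- 1 / ((1 + 1 / lam_SP) * (1 + lam_PF))
  c(s = (p + lam_PF * p) / lam_SP, p = p, f = lam_PF * p)
}

random_params <- function() {
  model_params(lam_W_SP = 1, lam_M_SP = 1, lam_W_PF = 100, lam_M_PF = 0.5,
               lam_agg = 10^stats::runif(1, 0, 6),
               gamma = stats::runif(1, 0.5, 30))
}

random_state <- function() {
  keratin_state(stats::runif(8, 0, 1))
}
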