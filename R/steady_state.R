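# Two independent routes to the dynamical equilibrium: stiff time
# integration (LSODA) and an algebraic reduction of the stationarity
# conditions.  Their agreement is a standing cross-check in the test suite.

new_steady_result <- function(state, converged, max_abs_derivative, tau_elapsed,
                              method, diagnostics = list()) {
  state <- keratin_state(state)
  Q <- tryCatch(Q_of(state), error = function(e) NA_real_)
  structure(list(state = state,
                 Q = Q,
                 chi_M = chi_M_of(state),
                 converged = converged,
                 max_abs_derivative = max_abs_derivative,
                 tau_elapsed = tau_elapsed,
                 method = method,
                 diagnostics = diagnostics),
            class = "keratin_steady")
}

#' Integrate the keratin network to its stationary state
#'
#' Advances the scaled system with [deSolve::lsoda()] — an implicit,
#' adaptive-step method appropriate for this stiff network, whose rates span
#' four or more orders of magnitude — until every phase-fraction time
#' derivative, converted to laboratory units via `k_minus`, falls below
#' `threshold`.  The criterion is evaluated on a cadence of `check_dtau`
#' scaled-time units; integration proceeds in geometrically growing chunks
#' so that long approaches to equilibrium do not pay a per-step checking
#' cost.
#'
#' @param params A [model_params()] object.
#' @param init Initial `keratin_state` (see [initial_state()]).
#' @param threshold Stationarity criterion on |d(fraction)/dt| in s^-1.
#'   Default `1e-10` s^-1.
#' @param k_minus Depolymerization rate (s^-1) used to convert scaled-time
#'   derivatives to s^-1; with the default rates the scaled criterion is
#'   `threshold / k_minus = 1e-7` per unit tau.
#' @param tau_max Give up after this much scaled time; the best state so far
#'   is then returned with `converged = FALSE` (never silently truncated).
#' @param check_dtau Cadence (scaled time) of the stationarity check.
#' @param rtol,atol Integrator tolerances.
#' @return A `keratin_steady` object: the state, its `Q` and `chi_M`,
#'   `converged`, `max_abs_derivative` (s^-1) at the accepted point,
#'   `tau_elapsed`, and `method = "integration"`.
#' @seealso [solve_algebraic()] for the independent algebraic route.
#' @examples
#' p <- model_params(gamma = 10, lam_agg = 1e4)
#' integrate_to_stationary(p, initial_state(0.25))
#' @export
integrate_to_stationary <- function(params, init,
                                    threshold = 1e-10, k_minus = 1e-3,
                                    tau_max = 1e7, check_dtau = 10,
                                    rtol = 1e-10, atol = 1e-12) {
  if (!inherits(params, "keratin_params")) params <- do.call(model_params, as.list(params))
  init <- keratin_state(init)
  stopifnot(threshold > 0, k_minus > 0, tau_max > 0, check_dtau > 0)
  scaled_threshold <- threshold / k_minus

  deriv <- function(t, y, parms) list(rhs_core(y, parms))

  y <- as.numeric(init)
  tau0 <- 0
  chunk <- max(check_dtau * 20, 200)
  n_chunks <- 0L
  best <- y
  best_res <- max(abs(rhs_core(y, params)))

  repeat {
    res0 <- max(abs(rhs_core(y, params)))
    if (res0 < scaled_threshold) {
      return(new_steady_result(y, TRUE, res0 * k_minus, tau0, "integration",
                               list(n_chunks = n_chunks)))
    }
    if (tau0 >= tau_max) break
    span <- min(chunk, tau_max - tau0)
    times <- seq(0, span, by = check_dtau)
    if (times[length(times)] < span) times <- c(times, span)
    out <- deSolve::lsoda(y, times, deriv, params, rtol = rtol, atol = atol)
    if (any(!is.finite(out))) {
      stop("integration failure: non-finite state encountered near tau = ",
           format(tau0), " (params: gamma = ", format(params$gamma),
           ", lam_agg = ", format(params$lam_agg), ")", call. = FALSE)
    }
    n_chunks <- n_chunks + 1L
    for (i in 2:nrow(out)) {
      yi <- out[i, -1L]
      ri <- max(abs(rhs_core(yi, params)))
      if (ri < best_res) {
        best <- yi
        best_res <- ri
      }
      if (ri < scaled_threshold) {
        return(new_steady_result(pmax(yi, 0), TRUE, ri * k_minus,
                                 tau0 + out[i, 1L], "integration",
                                 list(n_chunks = n_chunks)))
      }
    }
    y <- out[nrow(out), -1L]
    tau0 <- tau0 + span
    chunk <- min(chunk * 5, 1e6)
  }
  new_steady_result(pmax(best, 0), FALSE, best_res * k_minus, tau0,
                    "integration", list(n_chunks = n_chunks))
}

#' Algebraic steady state of the keratin network
#'
#' Setting the eight derivatives to zero gives, per species X,
#' `f_X = lam_X_PF * p_X`, `a_W = gamma * lam_agg * p_W * p_M`,
#' `a_M = lam_agg * p_W * p_M`, `s_X = (p_X + f_X + a_X) / lam_X_SP`.
#' Substituting these into the two species-conservation totals leaves a
#' pair of polynomial equations in `(p_W, p_M)`.  The first is linear in
#' `p_W` given `p_M`, so `p_W` is eliminated and the remaining scalar
#' equation in `p_M` is solved by bracketed root-finding on `[0, chi_M]`,
#' where a sign change is guaranteed; this yields the unique non-negative
#' root without multistart heuristics.
#'
#' This route involves no time stepping, making it both a fast path for
#' parameter scans and an independent oracle for the integrator.
#'
#' @param params A [model_params()] object.
#' @param chi_M Total mutant keratin fraction in `[0, 1]`.
#' @param k_minus Rate (s^-1) used only to report the residual
#'   `max_abs_derivative` in laboratory units.
#' @return A `keratin_steady` object with `method = "algebraic"`.
#' @export
solve_algebraic <- function(params, chi_M, k_minus = 1e-3) {
  if (!inherits(params, "keratin_params")) params <- do.call(model_params, as.list(params))
  if (!is.numeric(chi_M) || length(chi_M) != 1L || !is.finite(chi_M) ||
      chi_M < 0 || chi_M > 1) {
    stop("chi_M must be a single value in [0, 1]", call. = FALSE)
  }
  cw <- 1 + 1 / params$lam_W_SP
  cm <- 1 + 1 / params$lam_M_SP
  # wild-type conservation, linear in p_W given p_M
  p_W_of <- function(p_M) {
    (1 - chi_M) / (cw * ((1 + params$lam_W_PF) + params$gamma * params$lam_agg * p_M))
  }
  # mutant conservation residual; g(0) = -chi_M < 0, g(chi_M) > 0
  g <- function(p_M) {
    cm * (p_M * (1 + params$lam_M_PF) + params$lam_agg * p_W_of(p_M) * p_M) - chi_M
  }
  p_M <- if (chi_M == 0) 0 else {
    root <- tryCatch(
      stats::uniroot(g, interval = c(0, chi_M), tol = .Machine$double.eps),
      error = function(e) stop("algebraic steady-state root-finding failed for chi_M = ",
                               format(chi_M), ": ", conditionMessage(e), call. = FALSE))
    root$root
  }
  p_W <- p_W_of(p_M)
  if (p_W < 0 || p_M < 0) {
    stop("no non-negative steady-state root found (p_W = ", format(p_W),
         ", p_M = ", format(p_M), "); this should not occur for positive parameters",
         call. = FALSE)
  }
  agg <- params$lam_agg * p_W * p_M
  f_W <- params$lam_W_PF * p_W
  f_M <- params$lam_M_PF * p_M
  a_W <- params$gamma * agg
  a_M <- agg
  s_W <- (p_W + f_W + a_W) / params$lam_W_SP
  s_M <- (p_M + f_M + a_M) / params$lam_M_SP
  state <- c(s_W, s_M, p_W, p_M, f_W, f_M, a_W, a_M)
  res <- max(abs(rhs_core(state, params)))
  new_steady_result(state, TRUE, res * k_minus, NA_real_, "algebraic")
}

#' @export
print.keratin_steady <- function(x, ...) {
  cat("Keratin steady state (", x$method, ")\n", sep = "")
  cat("  converged:          ", x$converged, "\n")
  cat("  chi_M:              ", format(x$chi_M), "\n")
  cat("  Q:                  ", format(x$Q), "\n")
  cat("  max |d/dt| (s^-1):  ", format(x$max_abs_derivative), "\n")
  if (!is.na(x$tau_elapsed)) cat("  tau elapsed:        ", format(x$tau_elapsed), "\n")
  print(unclass(x$state))
  invisible(x)
}
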