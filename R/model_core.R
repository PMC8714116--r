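# Core reaction network: parameters, state, right-hand side, summaries.

#' Phase-fraction names, in canonical order
#'
#' All state vectors, matrices and file columns in the package use this
#' order: soluble, particulate, filamentous and aggregate keratin, wild-type
#' before mutant within each phase pair.
#'
#' @format Character vector of length 8.
#' @export
keratin_phases <- c("s_W", "s_M", "p_W", "p_M", "f_W", "f_M", "a_W", "a_M")

#' Dimensional rate constants of the keratin turnover network
#'
#' Bundles the kinetic constants of the two-species keratin cycle.  Keratin
#' in each species (wild-type `W`, mutant `M`) converts soluble -> particulate
#' at `k_X_SP` and particulate -> filamentous at `k_X_PF`; every assembled
#' form depolymerizes back to the soluble pool at the common rate `k_minus`.
#' Aggregates form by the bimolecular encounter of one wild-type and one
#' mutant particle at rate `k_agg`, incorporating `gamma` units of wild-type
#' keratin per unit of mutant keratin (the binding asymmetry).
#'
#' Defaults are the literature-derived values for keratin 14 turnover
#' (mutant filament assembly 200-fold slower than wild-type) and a total
#' cytoplasmic keratin concentration of 1 mM.  `k_agg` and `gamma` have not
#' been measured; their defaults sit in the regime where aggregate burden
#' peaks at low mutant fractions, and every analysis function takes them as
#' free parameters.
#'
#' @param k_W_SP,k_M_SP Soluble -> particulate rates (s^-1).
#' @param k_W_PF,k_M_PF Particulate -> filamentous rates (s^-1).
#' @param k_minus Common depolymerization rate (s^-1).
#' @param k_agg Bimolecular aggregation rate (M^-1 s^-1).
#' @param gamma Dimensionless wild-type:mutant binding asymmetry (> 0).
#' @param K_total Total keratin concentration (M), assumed constant.
#' @return An object of class `keratin_rates` (a named list).
#' @seealso [nondimensionalize()], [model_params()]
#' @examples
#' rates <- rate_constants()
#' nondimensionalize(rates)
#' @export
rate_constants <- function(k_W_SP = 1.0e-3, k_M_SP = 1.0e-3,
                           k_W_PF = 1.0e-1, k_M_PF = 5.0e-4,
                           k_minus = 1.0e-3, k_agg = 1.0e4,
                           gamma = 10, K_total = 1.0e-3) {
  r <- list(k_W_SP = k_W_SP, k_M_SP = k_M_SP, k_W_PF = k_W_PF,
            k_M_PF = k_M_PF, k_minus = k_minus, k_agg = k_agg,
            gamma = gamma, K_total = K_total)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid rate constant: '", nm, "' must be a single finite value > 0",
           call. = FALSE)
    }
  }
  structure(r, class = "keratin_rates")
}

#' Non-dimensional model parameters
#'
#' The analysis works in scaled time tau = k_minus * t with concentrations
#' expressed as fractions of `K_total`.  Each first-order rate becomes
#' `lam = k / k_minus` and the bimolecular aggregation rate becomes
#' `lam_agg = k_agg * K_total / k_minus`.  `gamma` is already dimensionless.
#'
#' @param lam_W_SP,lam_M_SP Scaled soluble -> particulate rates.
#' @param lam_W_PF,lam_M_PF Scaled particulate -> filamentous rates.
#' @param lam_agg Scaled aggregation rate.
#' @param gamma Binding asymmetry (> 0).
#' @return An object of class `keratin_params`.
#' @export
model_params <- function(lam_W_SP = 1, lam_M_SP = 1,
                         lam_W_PF = 100, lam_M_PF = 0.5,
                         lam_agg = 1e4, gamma = 10) {
  p <- list(lam_W_SP = lam_W_SP, lam_M_SP = lam_M_SP, lam_W_PF = lam_W_PF,
            lam_M_PF = lam_M_PF, lam_agg = lam_agg, gamma = gamma)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid model parameter: '", nm, "' must be a single finite value > 0",
           call. = FALSE)
    }
  }
  structure(p, class = "keratin_params")
}

#' Convert dimensional rate constants to non-dimensional parameters
#'
#' @param rates A [rate_constants()] object.
#' @return A [model_params()] object with `lam_X = k_X / k_minus`,
#'   `lam_agg = k_agg * K_total / k_minus`, `gamma` passed through.
#' @export
nondimensionalize <- function(rates) {
  if (!inherits(rates, "keratin_rates")) rates <- do.call(rate_constants, as.list(rates))
  model_params(lam_W_SP = rates$k_W_SP / rates$k_minus,
               lam_M_SP = rates$k_M_SP / rates$k_minus,
               lam_W_PF = rates$k_W_PF / rates$k_minus,
               lam_M_PF = rates$k_M_PF / rates$k_minus,
               lam_agg = rates$k_agg * rates$K_total / rates$k_minus,
               gamma = rates$gamma)
}

#' Construct a keratin phase-fraction state
#'
#' A state is a named numeric vector of the 8 phase fractions in the order
#' of [keratin_phases]. Fractions must be finite and non-negative; a
#' *physical* state additionally sums to 1, which [initial_state()]
#' guarantees but arbitrary states (e.g. probes of the vector field) need
#' not.
#'
#' @param x Numeric vector of length 8 (named or in canonical order).
#' @return A named numeric vector of class `keratin_state`.
#' @export
keratin_state <- function(x) {
  if (length(x) != 8L) stop("a keratin state has exactly 8 components", call. = FALSE)
  x <- as.numeric(x)
  names(x) <- keratin_phases
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("invalid state: all phase fractions must be finite and >= 0", call. = FALSE)
  }
  structure(x, class = "keratin_state")
}

#' Initial condition with a prescribed total mutant fraction
#'
#' @param chi_M Total mutant keratin fraction in `[0, 1]`.
#' @param allocation `"all_soluble"` puts all keratin in the soluble phase
#'   (`s_W = 1 - chi_M`, `s_M = chi_M`); `"uniform"` spreads each species
#'   evenly over its four phases.  The steady state does not depend on this
#'   choice (asserted in the test suite), so it only sets the transient.
#' @return A `keratin_state` summing to 1 with mutant total `chi_M`.
#' @export
initial_state <- function(chi_M, allocation = c("all_soluble", "uniform")) {
  allocation <- match.arg(allocation)
  if (!is.numeric(chi_M) || length(chi_M) != 1L || !is.finite(chi_M) ||
      chi_M < 0 || chi_M > 1) {
    stop("chi_M must be a single value in [0, 1]", call. = FALSE)
  }
  x <- numeric(8)
  if (allocation == "all_soluble") {
    x[1] <- 1 - chi_M
    x[2] <- chi_M
  } else {
    x[c(1, 3, 5, 7)] <- (1 - chi_M) / 4
    x[c(2, 4, 6, 8)] <- chi_M / 4
  }
  keratin_state(x)
}

# Unchecked vector field, shared by the exported rhs and the integrator.
# y follows the canonical phase order; lam is the keratin_params list.
rhs_core <- function(y, lam) {
  agg <- lam$lam_agg * y[3L] * y[4L]
  c(-lam$lam_W_SP * y[1L] + (y[3L] + y[5L] + y[7L]),
    -lam$lam_M_SP * y[2L] + (y[4L] + y[6L] + y[8L]),
    lam$lam_W_SP * y[1L] - y[3L] - lam$lam_W_PF * y[3L] - lam$gamma * agg,
    lam$lam_M_SP * y[2L] - y[4L] - lam$lam_M_PF * y[4L] - agg,
    lam$lam_W_PF * y[3L] - y[5L],
    lam$lam_M_PF * y[4L] - y[6L],
    lam$gamma * agg - y[7L],
    agg - y[8L])
}

#' Time derivatives of the keratin phase fractions
#'
#' Evaluates the reaction network's vector field in scaled time tau.
#' All reactions are first order except aggregate formation, which is
#' proportional to the product `p_W * p_M` of the two particulate pools;
#' each aggregation event removes `gamma` units of wild-type and 1 unit of
#' mutant particulate keratin and deposits them in the respective aggregate
#' pools.  By construction the four wild-type derivatives sum to zero, as do
#' the four mutant ones, so both species totals are conserved exactly.
#'
#' @param state A `keratin_state` (or coercible vector of 8 non-negative
#'   fractions).
#' @param params A [model_params()] object.
#' @return Named numeric vector of d(fraction)/d(tau), canonical order.
#' @export
keratin_rhs <- function(state, params) {
  state <- keratin_state(state)
  if (!inherits(params, "keratin_params")) params <- do.call(model_params, as.list(params))
  d <- rhs_core(as.numeric(state), params)
  names(d) <- keratin_phases
  d
}

#' Dimensional form of the vector field
#'
#' Same network written for concentrations (M) and laboratory time (s).
#' Used to verify that the scaled system is an exact reparametrization of
#' the dimensional one.
#'
#' @param conc Named numeric vector of 8 concentrations (M), canonical
#'   phase order (uppercase interpretation of [keratin_phases]).
#' @param rates A [rate_constants()] object.
#' @return Named numeric vector of d(concentration)/dt in M s^-1.
#' @export
keratin_rhs_dimensional <- function(conc, rates) {
  if (!inherits(rates, "keratin_rates")) rates <- do.call(rate_constants, as.list(rates))
  y <- as.numeric(conc)
  if (length(y) != 8L || any(!is.finite(y)) || any(y < 0)) {
    stop("invalid state: 8 finite non-negative concentrations required", call. = FALSE)
  }
  agg <- rates$k_agg * y[3L] * y[4L]
  km <- rates$k_minus
  d <- c(-rates$k_W_SP * y[1L] + km * (y[3L] + y[5L] + y[7L]),
         -rates$k_M_SP * y[2L] + km * (y[4L] + y[6L] + y[8L]),
         rates$k_W_SP * y[1L] - km * y[3L] - rates$k_W_PF * y[3L] - rates$gamma * agg,
         rates$k_M_SP * y[2L] - km * y[4L] - rates$k_M_PF * y[4L] - agg,
         rates$k_W_PF * y[3L] - km * y[5L],
         rates$k_M_PF * y[4L] - km * y[6L],
         rates$gamma * agg - km * y[7L],
         agg - km * y[8L])
  names(d) <- keratin_phases
  d
}

#' Total mutant keratin fraction of a state
#'
#' `chi_M = s_M + p_M + f_M + a_M`, the summary the parameter scans sweep.
#'
#' @param state A `keratin_state`.
#' @return Fraction in `[0, 1]` for physical states.
#' @export
chi_M_of <- function(state) {
  state <- keratin_state(state)
  unname(state[2L] + state[4L] + state[6L] + state[8L])
}

#' Aggregate-to-filament ratio Q of a state
#'
#' `Q = (a_W + a_M + p_W + p_M) / (f_W + f_M)`: the non-filamentous
#' assembled keratin relative to the filament network, the model's
#' observable aggregate burden.
#'
#' @param state A `keratin_state`.
#' @param guard Filament-total threshold below which the state is declared
#'   degenerate instead of returning an unbounded ratio.  At steady state
#'   with positive parameters the filament pools never vanish, so the guard
#'   only fires on pathological inputs.
#' @return The ratio (dimensionless).
#' @export
Q_of <- function(state, guard = 1e-12) {
  state <- keratin_state(state)
  fil <- state[5L] + state[6L]
  if (fil < guard) {
    stop("degenerate state: filament total ", format(fil),
         " below guard threshold ", format(guard), call. = FALSE)
  }
  unname((state[7L] + state[8L] + state[3L] + state[4L]) / fil)
}

#' @export
print.keratin_rates <- function(x, ...) {
  cat("Keratin turnover rate constants:\n")
  cat(sprintf("  %-8s %s\n", names(x), vapply(x, format, "")), sep = "")
  invisible(x)
}

#' @export
print.keratin_params <- function(x, ...) {
  cat("Non-dimensional keratin model parameters:\n")
  cat(sprintf("  %-9s %s\n", names(x), vapply(x, format, "")), sep = "")
  invisible(x)
}

#' @export
print.keratin_state <- function(x, ...) {
  cat("Keratin phase fractions (total ", format(sum(x)), "):\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}
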