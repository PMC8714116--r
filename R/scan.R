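# Mutant-fraction sweeps and (gamma, lam_agg) phase maps of the peak
# aggregate burden.

#' Sweep the mutant fraction and locate the peak aggregate burden
#'
#' Computes the stationary aggregate-to-filament ratio `Q` at every point of
#' a `chi_M` grid via the algebraic solver, then (optionally) sharpens the
#' maximizer by golden-section search between the grid neighbours of the
#' coarse argmax.  Ties in the coarse argmax break toward the smallest
#' `chi_M` so output is deterministic.
#'
#' With the default wild-type/mutant rates, `Q` is anchored at
#' `1 / lam_W_PF` at `chi_M = 0` and `1 / lam_M_PF` at `chi_M = 1`
#' (at stationarity `f_X = lam_X_PF * p_X`, so the single-species ratio is
#' forced); between the endpoints aggregation can push `Q` far higher.
#'
#' @param params A [model_params()] object.
#' @param chi_grid Strictly increasing grid in `[0, 1]`, at least 3 points.
#'   The default step of 0.005 keeps the coarse argmax error well below the
#'   0.15-wide window the phase-region analysis cares about.
#' @param refine Sharpen the maximizer by [stats::optimize()] (golden
#'   section / parabolic) to `refine_tol` in `chi_M`.  The refined peak is
#'   never reported below the coarse-grid maximum.
#' @param refine_tol Tolerance of the refinement in `chi_M`.
#' @param spot_check Cross-validate the peak against the stiff integrator
#'   and record the relative discrepancy (a warning is raised above
#'   `1e-5`).
#' @return A `chi_sweep` object: `chi_grid`, `Q`, the 8-column `states`
#'   matrix, `chi_M_max`, `Q_max`, the params, and any spot-check record.
#' @examples
#' sw <- sweep_chi(model_params(gamma = 10, lam_agg = 1e4),
#'                 chi_grid = seq(0, 1, by = 0.02), spot_check = FALSE)
#' c(sw$chi_M_max, sw$Q_max)
#' @export
sweep_chi <- function(params, chi_grid = seq(0, 1, by = 0.005),
                      refine = TRUE, refine_tol = 1e-4, spot_check = TRUE) {
  if (!inherits(params, "keratin_params")) params <- do.call(model_params, as.list(params))
  n <- length(chi_grid)
  if (n < 3L || any(diff(chi_grid) <= 0) || chi_grid[1] < 0 || chi_grid[n] > 1) {
    stop("chi_grid must be strictly increasing within [0, 1] with >= 3 points",
         call. = FALSE)
  }
  states <- matrix(NA_real_, n, 8L, dimnames = list(NULL, keratin_phases))
  Q <- numeric(n)
  for (i in seq_len(n)) {
    sol <- solve_algebraic(params, chi_grid[i])
    if (is.na(sol$Q)) {
      stop("degenerate Q (vanishing filament pool) at chi_M = ",
           format(chi_grid[i]), call. = FALSE)
    }
    states[i, ] <- sol$state
    Q[i] <- sol$Q
  }
  i_max <- which.max(Q)             # first maximum: ties -> smallest chi_M
  chi_M_max <- chi_grid[i_max]
  Q_max <- Q[i_max]
  if (isTRUE(refine)) {
    lo <- chi_grid[max(i_max - 1L, 1L)]
    hi <- chi_grid[min(i_max + 1L, n)]
    if (hi > lo) {
      opt <- stats::optimize(function(ch) solve_algebraic(params, ch)$Q,
                             interval = c(lo, hi), maximum = TRUE,
                             tol = refine_tol)
      if (opt$objective > Q_max) {
        chi_M_max <- opt$maximum
        Q_max <- opt$objective
      }
    }
  }
  check <- NULL
  if (isTRUE(spot_check)) {
    ss <- integrate_to_stationary(params, initial_state(chi_M_max))
    rel <- abs(ss$Q - Q_max) / max(abs(Q_max), .Machine$double.xmin)
    check <- list(chi_M = chi_M_max, Q_integrated = ss$Q, rel_discrepancy = rel)
    if (!is.na(rel) && rel > 1e-5) {
      warning("integrator cross-check at the peak disagrees with the algebraic ",
              "solver (relative ", format(rel), ")", call. = FALSE)
    }
  }
  structure(list(chi_grid = chi_grid, Q = Q, states = states,
                 chi_M_max = chi_M_max, Q_max = Q_max,
                 params = params, spot_check = check),
            class = "chi_sweep")
}

#' Map the peak aggregate burden over the (gamma, lam_agg) plane
#'
#' Runs [sweep_chi()] in every grid cell and collects the maximizing mutant
#' fraction (`chi_M_max_map`), the peak ratio (`Q_max_map`) and a mask of
#' the cells whose maximizer falls strictly inside the `region` window —
#' by default 15–30%, the window matching the cell-culture observation that
#' aggregate burden peaks at low mutant expression.  A failing cell is
#' recorded and left `NA`; the map always completes.
#'
#' @param gamma_grid Asymmetry axis; default 21 log-spaced points on
#'   `[1, 20]`.
#' @param lam_agg_grid Aggregation-rate axis; default 25 log-spaced points
#'   on `[1, 1e6]`.
#' @param chi_grid Mutant-fraction grid passed to each sweep.
#' @param base_params Parameters whose turnover rates are held fixed while
#'   `gamma` and `lam_agg` take the grid values.
#' @param region `c(lo, hi)` bounds of the window of interest.
#' @param refine,refine_tol Passed to [sweep_chi()].
#' @param cross_validate Spot-check every `cross_validate`-th cell against
#'   the integrator (0 disables).
#' @return A `phase_map` object; see [region_extract()] and
#'   [as.data.frame.phase_map()].
#' @export
phase_map <- function(gamma_grid = exp(seq(log(1), log(20), length.out = 21)),
                      lam_agg_grid = 10^seq(0, 6, length.out = 25),
                      chi_grid = seq(0, 1, by = 0.005),
                      base_params = model_params(),
                      region = c(0.15, 0.30),
                      refine = TRUE, refine_tol = 1e-4,
                      cross_validate = 20) {
  if (!inherits(base_params, "keratin_params")) {
    base_params <- do.call(model_params, as.list(base_params))
  }
  if (length(gamma_grid) < 1L || length(lam_agg_grid) < 1L) {
    stop("phase-map axes must be non-empty", call. = FALSE)
  }
  ng <- length(gamma_grid)
  nl <- length(lam_agg_grid)
  chi_M_max_map <- matrix(NA_real_, ng, nl)
  Q_max_map <- matrix(NA_real_, ng, nl)
  failures <- list()
  cell <- 0L
  for (i in seq_len(ng)) {
    for (j in seq_len(nl)) {
      cell <- cell + 1L
      p <- base_params
      p$gamma <- gamma_grid[i]
      p$lam_agg <- lam_agg_grid[j]
      spot <- cross_validate > 0 && (cell %% cross_validate == 1L)
      sw <- tryCatch(sweep_chi(p, chi_grid, refine = refine,
                               refine_tol = refine_tol, spot_check = spot),
                     error = function(e) e)
      if (inherits(sw, "error")) {
        failures[[length(failures) + 1L]] <-
          list(gamma = gamma_grid[i], lam_agg = lam_agg_grid[j],
               message = conditionMessage(sw))
      } else {
        chi_M_max_map[i, j] <- sw$chi_M_max
        Q_max_map[i, j] <- sw$Q_max
      }
    }
  }
  out <- structure(list(gamma_grid = gamma_grid, lam_agg_grid = lam_agg_grid,
                        chi_M_max_map = chi_M_max_map, Q_max_map = Q_max_map,
                        region = region, region_mask = NULL,
                        base_params = base_params, failures = failures),
                   class = "phase_map")
  out$region_mask <- region_extract(out, region[1], region[2])
  out
}

#' Mask the phase map to a window of maximizer locations
#'
#' @param map A [phase_map()] object.
#' @param lo,hi Strict bounds, `0 <= lo < hi <= 1`.
#' @return Logical matrix, `TRUE` exactly where `lo < chi_M_max < hi`
#'   (failed/`NA` cells are `FALSE`).
#' @export
region_extract <- function(map, lo = 0.15, hi = 0.30) {
  if (!inherits(map, "phase_map")) stop("map must be a phase_map", call. = FALSE)
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    stop("region bounds must satisfy 0 <= lo < hi <= 1", call. = FALSE)
  }
  m <- map$chi_M_max_map > lo & map$chi_M_max_map < hi
  m[is.na(m)] <- FALSE
  m
}

#' @describeIn sweep_chi Tabular view: one row per grid point with `chi_M`,
#'   `Q` and the 8 phase fractions.
#' @param x A `chi_sweep` object.
#' @param ... Unused.
#' @export
as.data.frame.chi_sweep <- function(x, ...) {
  data.frame(chi_M = x$chi_grid, Q = x$Q, x$states, check.names = FALSE)
}

#' Tabular view of a phase map
#'
#' One row per (gamma, lam_agg) cell with the maximizer location, the peak
#' ratio and the region flag.
#'
#' @param x A `phase_map` object.
#' @param ... Unused.
#' @return A data.frame with columns `gamma`, `lam_agg`, `chi_M_max`,
#'   `Q_max`, `in_region`.
#' @export
as.data.frame.phase_map <- function(x, ...) {
  g <- rep(x$gamma_grid, times = length(x$lam_agg_grid))
  l <- rep(x$lam_agg_grid, each = length(x$gamma_grid))
  data.frame(gamma = g, lam_agg = l,
             chi_M_max = as.vector(x$chi_M_max_map),
             Q_max = as.vector(x$Q_max_map),
             in_region = as.vector(x$region_mask))
}

#' @export
print.chi_sweep <- function(x, ...) {
  cat("chi_M sweep over", length(x$chi_grid), "points",
      "(gamma =", format(x$params$gamma),
      ", lam_agg =", format(x$params$lam_agg), ")\n")
  cat("  chi_M_max:", format(x$chi_M_max), "  Q_max:", format(x$Q_max), "\n")
  if (!is.null(x$spot_check)) {
    cat("  integrator cross-check rel. discrepancy:",
        format(x$spot_check$rel_discrepancy), "\n")
  }
  invisible(x)
}

#' @export
print.phase_map <- function(x, ...) {
  cat("Phase map:", length(x$gamma_grid), "gamma x",
      length(x$lam_agg_grid), "lam_agg cells\n")
  cat("  cells in (", x$region[1], ",", x$region[2], ") window:",
      sum(x$region_mask), "\n")
  if (length(x$failures)) cat("  failed cells:", length(x$failures), "\n")
  invisible(x)
}

#' Base-graphics view of a mutant-fraction sweep
#'
#' @param x A `chi_sweep` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.chi_sweep <- function(x, ...) {
  graphics::plot(x$chi_grid, x$Q, type = "l", log = "y",
                 xlab = expression(chi[M]), ylab = "Q",
                 main = sprintf("gamma = %.3g, lam_agg = %.3g",
                                x$params$gamma, x$params$lam_agg), ...)
  graphics::abline(v = x$chi_M_max, lty = 2)
}
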