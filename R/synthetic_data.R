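# Seeded generators of synthetic observations with the statistical
# structure the inference stage assumes: lognormal noise on the
# aggregate-to-filament ratio, and a binomial cell-population readout
# through a saturating link.

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate noisy observations of the aggregate-to-filament ratio
#'
#' Emulates replicated measurements of the stationary aggregate burden `Q`
#' across cell lines expressing different total mutant fractions — the
#' computational analogue of image-based aggregate scoring and pellet-
#' fraction quantification.  Noise is multiplicative lognormal,
#' `Q_obs = Q_true * exp(eps)`, `eps ~ N(0, noise_sigma^2)`, because `Q` is
#' a positive ratio spanning orders of magnitude across the sweep.
#'
#' @param true_params [model_params()] used to compute the noiseless curve
#'   (via [solve_algebraic()]).
#' @param chi_points Mutant fractions at which observations are made.  The
#'   default 50 points span `[0.02, 0.98]`.
#' @param noise_sigma Standard deviation of the log-scale noise (>= 0).
#' @param n_reps Replicates per point (>= 1).
#' @param seed Integer seed; the same seed reproduces `Q_obs` bit for bit.
#' @return A `keratin_dataset`: `chi_points`, `Q_true`, the
#'   `length(chi_points) x n_reps` matrix `Q_obs`, `noise_sigma`, `seed`
#'   and `true_params`.  Points with a degenerate (filament-free) `Q` are
#'   excluded with a warning.
#' @export
generate_q_observations <- function(true_params,
                                    chi_points = seq(0.02, 0.98, length.out = 50),
                                    noise_sigma = 0.05, n_reps = 3, seed = 1L) {
  if (!inherits(true_params, "keratin_params")) {
    true_params <- do.call(model_params, as.list(true_params))
  }
  stopifnot(noise_sigma >= 0, n_reps >= 1)
  Q_true <- vapply(chi_points, function(ch) {
    sol <- solve_algebraic(true_params, ch)
    sol$Q
  }, numeric(1))
  bad <- is.na(Q_true)
  if (any(bad)) {
    warning("excluding ", sum(bad), " chi_M point(s) with degenerate Q",
            call. = FALSE)
    chi_points <- chi_points[!bad]
    Q_true <- Q_true[!bad]
  }
  n <- length(chi_points)
  if (n == 0L) stop("no usable chi_M points remain", call. = FALSE)
  Q_obs <- with_seed(seed, {
    eps <- matrix(stats::rnorm(n * n_reps, mean = 0, sd = noise_sigma), n, n_reps)
    Q_true * exp(eps)
  })
  structure(list(chi_points = chi_points, Q_true = Q_true, Q_obs = Q_obs,
                 noise_sigma = noise_sigma, n_reps = n_reps, seed = seed,
                 true_params = true_params),
            class = "keratin_dataset")
}

#' @describeIn generate_q_observations Long-format view with columns
#'   `chi_M`, `replicate`, `Q_obs`.
#' @param x A `keratin_dataset`.
#' @param ... Unused.
#' @export
as.data.frame.keratin_dataset <- function(x, ...) {
  n <- length(x$chi_points)
  data.frame(chi_M = rep(x$chi_points, times = x$n_reps),
             replicate = rep(seq_len(x$n_reps), each = n),
             Q_obs = as.vector(x$Q_obs))
}

#' Simulate an aggregate-positive cell count
#'
#' Draws the number of aggregate-positive cells in a population, with each
#' cell flagged positive independently with probability
#' `p = Q / (Q + link_scale)` — a saturating, monotone-in-`Q` link from the
#' model's aggregate burden to the fraction of cells scored as containing
#' aggregates.  The link is a modelling convenience for demonstrating the
#' non-monotonic burden-versus-mutant-fraction pattern, not a measured
#' calibration.
#'
#' @param true_params [model_params()] for the underlying steady state.
#' @param chi_M Mutant fraction(s); vectorized.
#' @param n_cells Population size(s) (>= 1), recycled against `chi_M`.
#' @param link_scale Positive scale of the link; larger values need more
#'   aggregate burden to flag a cell (`Inf` flags none).
#' @param seed Integer seed for reproducible draws.
#' @return A `cell_population` data.frame with columns `chi_M`, `n_cells`,
#'   `n_with_aggregates`, `p`; `link_scale` and `seed` as attributes.
#' @export
generate_cell_population <- function(true_params, chi_M, n_cells,
                                     link_scale = 1, seed = 1L) {
  if (!inherits(true_params, "keratin_params")) {
    true_params <- do.call(model_params, as.list(true_params))
  }
  stopifnot(all(n_cells >= 1), link_scale > 0)
  k <- max(length(chi_M), length(n_cells))
  chi_M <- rep_len(chi_M, k)
  n_cells <- rep_len(as.integer(n_cells), k)
  Q <- vapply(chi_M, function(ch) solve_algebraic(true_params, ch)$Q, numeric(1))
  p <- if (is.infinite(link_scale)) rep(0, k) else Q / (Q + link_scale)
  n_pos <- with_seed(seed, stats::rbinom(k, size = n_cells, prob = p))
  out <- data.frame(chi_M = chi_M, n_cells = n_cells,
                    n_with_aggregates = n_pos, p = p)
  attr(out, "link_scale") <- link_scale
  attr(out, "seed") <- seed
  class(out) <- c("cell_population", class(out))
  out
}

#' @export
print.keratin_dataset <- function(x, ...) {
  cat("Synthetic Q observations:", length(x$chi_points), "chi_M points x",
      x$n_reps, "replicates, sigma =", format(x$noise_sigma),
      ", seed =", x$seed, "\n")
  cat("  truth: gamma =", format(x$true_params$gamma),
      ", lam_agg =", format(x$true_params$lam_agg), "\n")
  invisible(x)
}
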