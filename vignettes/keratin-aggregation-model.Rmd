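---
title: "Modelling keratin aggregation from WT-mutant co-expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling keratin aggregation from WT-mutant co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kerataggr)
```

## The model and its assumptions

Keratin in a keratinocyte cycles between coarse-grained phases: very small
oligomers (soluble, `s`), intermediate-size oligomers (particulate, `p`)
and assembled filaments (`f`). When a mutant keratin species is
co-expressed with wild-type (WT), a fourth phase appears: aggregates
(`a`). `kerataggr` tracks the eight phase fractions
`(s_W, s_M, p_W, p_M, f_W, f_M, a_W, a_M)` of the constant total keratin
pool with mass-action kinetics:

* every reaction is first order except aggregate formation, which is
  bimolecular in the two particulate pools (`lam_agg * p_W * p_M`);
* each aggregation event incorporates `gamma` units of WT keratin per
  unit of mutant keratin — the binding asymmetry that is the model's
  central hypothesis;
* all assembled forms depolymerize back to the soluble phase one unit at
  a time, at a single common rate, so in scaled time every loss term has
  unit rate;
* the total keratin pool is constant (no synthesis or degradation), and
  consequently the WT and mutant totals are each conserved exactly — the
  vector field satisfies both conservation laws by construction, which
  the test suite asserts to cancellation precision.

The model deliberately omits spatial transport of aggregates,
proteasome-mediated aggregate disposal, stochastic kinetics and
cell-to-cell rate variability. It is a minimal steady-state description:
time courses are a byproduct of finding the equilibrium, not a
deliverable.

## Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `lam_W_SP`, `lam_M_SP` | scaled soluble→particulate rates | 1 | literature turnover fits; mutation does not impair particle formation |
| `lam_W_PF` | scaled WT particulate→filament rate | 100 | literature fit: WT filament assembly is fast |
| `lam_M_PF` | scaled mutant particulate→filament rate | 0.5 | literature fit: the mutation slows filament assembly 200-fold |
| `lam_agg` | scaled aggregation rate `k_agg * K_total / k_minus` | free; default `1e4` | unmeasured; default sits in the experimentally matching regime |
| `gamma` | WT:mutant asymmetry of aggregate composition | free; default `10` | unmeasured; default sits in the experimentally matching regime |
| `K_total` | total keratin concentration | `1e-3` M | literature value; enters only through `lam_agg` |
| `k_minus` | depolymerization rate | `1e-3` s⁻¹ | literature value; sets the time scale `tau = k_minus * t` |

The dimensional constructor `rate_constants()` carries the s⁻¹ / M⁻¹s⁻¹
values; `nondimensionalize()` maps them onto the scaled parameters, and
the equivalence of the dimensional and scaled systems is itself a test.

## Finding the steady state

Two independent routes:

1. **Stiff integration** (`integrate_to_stationary()`). The scaled rates
   span four or more orders of magnitude, so the system is stiff and an
   implicit, adaptive-step method is required; we use `deSolve::lsoda()`.
   Stationarity is declared when every |d(fraction)/dt|, converted to
   laboratory units via `k_minus`, falls below a threshold of
   `1e-10` s⁻¹ (configurable). Because `dx/dtau = (1/k_minus) dx/dt`,
   the scaled-time criterion is `threshold / k_minus = 1e-7` per unit tau
   at the default rates. The criterion is checked on a cadence of 10
   scaled-time units — cheap, and robust against transient plateaus —
   inside geometrically growing integration chunks, up to `tau_max = 1e7`;
   hitting `tau_max` returns `converged = FALSE` with the best state so
   far, never a silent truncation.
2. **Algebraic reduction** (`solve_algebraic()`). Setting the derivatives
   to zero gives `f_X = lam_X_PF * p_X`, `a_W = gamma * lam_agg * p_W * p_M`,
   `a_M = lam_agg * p_W * p_M` and `s_X = (p_X + f_X + a_X)/lam_X_SP`;
   substituting into the two species totals leaves two polynomial
   equations in `(p_W, p_M)`. The first is linear in `p_W` given `p_M`,
   so the problem reduces to one scalar equation in `p_M` with a
   guaranteed sign change on `[0, chi_M]`, solved by bracketed
   root-finding (`uniroot` at machine tolerance). This yields the unique
   non-negative root without multistart heuristics.

The two routes agree to ~1e-14 relative at typical parameters. One
numerical subtlety: the stopping residual bounds the remaining distance
to the fixed point *along the slow modes*, so a residual of `1e-7`
(scaled) can leave relative errors near `1e-4` in small components.
Tests that assert field-level agreement at relative `1e-5` across random
parameter draws therefore tighten the threshold to `1e-13` s⁻¹; this is
a property of stopping criteria generally, not of this system.

Uniqueness of the steady state is asserted empirically, not proven: the
bracketed root is unique and integration from two different initial
allocations (`all_soluble` vs `uniform` — the model's own literature does
not state initial conditions, so all-soluble split by `chi_M` is the
default) converges to the same state to relative `1e-6`. This
initial-condition check doubles as a multistability probe.

Degenerate inputs: `Q_of()` declares a state degenerate when the filament
total falls below `1e-12` rather than returning infinity; at steady state
with positive parameters the filament pools never vanish, so the guard
only fires on pathological inputs.

## Sweeps and the phase map

`sweep_chi()` evaluates `Q` on a `chi_M` grid (default step 0.005 —
small against the 0.15-wide window of interest) via the algebraic fast
path, then sharpens the maximizer by golden-section search between the
grid neighbours of the coarse argmax (tolerance `1e-4` in `chi_M`).
Ties break toward the smallest `chi_M` for deterministic output, and the
refined peak is never reported below the coarse maximum. The integrator
spot-checks the peak (1 cell in 20 on phase maps).

Two anchors hold for every parameter cell, because stationarity forces
the single-species ratio: `Q(0) = 1/lam_W_PF = 0.01` and
`Q(1) = 1/lam_M_PF = 2`. The mutant-side value is "small" only relative
to the interior peaks (tens); the turnover rates themselves fix it at 2,
and the package reports the computed value rather than reinterpreting the
rates.

`phase_map()` tiles (γ, λ_agg) — default 21 log-spaced γ in [1, 20] × 25
log-spaced λ_agg in [1, 1e6]; the axes mirror the ranges over which the
regime claims are stated, as no canonical grid exists — and masks cells
whose maximizer lies strictly inside the 15–30% window. Per-cell failures
are recorded and left `NA`; the map always completes. Heatmap rendering is
a convenience (`plot()` on a sweep), not a verification surface.

A boundary nuance worth knowing: at γ just above 10 the in-window cells
at λ_agg = 1e4 carry peak burdens Q_max in the high teens, but as γ grows
the maximizer slides *below* 0.15 at λ_agg = 1e4 (e.g. ~0.150 at γ = 12),
leaving only the λ_agg = 1e3 cells strictly inside the window — and those
peak near Q_max ≈ 6–7 rather than ≥ 10. The strict window therefore
splits the "order-of-magnitude aggregate dominance" claim: it holds on
the high-λ_agg edge of the window and not on its low-λ_agg interior. The
acceptance suite computes and reports exactly this, and the corresponding
check is knowingly left failing rather than widened.

## Synthetic data

`generate_q_observations()` emulates replicated measurements of the
aggregate burden across cell lines with different mutant fractions — the
computational analogue of scoring cells for aggregates and quantifying
pellet-fraction keratin. Design choices:

* **lognormal noise** (`Q_obs = Q_true * exp(N(0, sigma^2))`): `Q` is a
  positive ratio spanning decades, so multiplicative noise is the natural
  error model, and it makes least squares on `log Q` the
  maximum-likelihood criterion for the fitter;
* default 50 points on [0.02, 0.98], avoiding endpoints where the
  cell-level link illustration degenerates; `sigma = 0.05`, 3 replicates —
  a precision an imaging readout could plausibly achieve, fixed once;
* seeded determinism, with the caller's RNG stream left untouched.

`generate_cell_population()` maps `Q` to a fraction of aggregate-positive
cells through the saturating link `p = Q/(Q + link_scale)`. No measured
calibration from burden to cell counts exists; any monotone saturating
link reproduces the qualitative non-monotone pattern (most positive cells
at low mutant fraction), and the link is explicitly not claimed to be the
experimental mapping.

What the generator does *not* emulate: cell-to-cell rate variability,
measurement error structure of Western blots, or count noise in `Q`
itself. Passing recovery tests therefore show identifiability of
(γ, λ_agg) under the model's own noise assumptions, not robustness to
real-data misspecification.

## Parameter recovery

`fit_params()` minimizes the sum of squared `log Q` residuals over a box
in `(log10 gamma, log10 lam_agg)` — log10 space because the sweeps show
behaviour organized by orders of magnitude. A 5×5 multistart grid ranks
starting points; the best three are refined by Nelder–Mead with a
quadratic out-of-box penalty; the best local optimum is reported together
with an evaluation count and a **flatness diagnostic**: the loss
variation along each axis (±0.1 log10) at the optimum. The diagnostic
surfaces unidentifiable directions instead of hiding them — γ is
invisible when the data carry no aggregation signal (tiny λ_agg), and the
test suite checks the objective is flat along γ to `1e-8` in that case.

Zero-noise data are recovered to `1e-3` in log10 (solver tolerance); at
`sigma = 0.05` with 50 points × 3 replicates both estimates land within
±0.2 log10 of truth, a tolerance fixed by a pilot over independent seeds
and kept as a repo constant.

## Problem sizes

The shipped tests use 201-point `chi_M` grids, 25–100 random parameter
draws for the cross-solver properties, 3×3 or smaller phase maps in unit
tests, and a handful of fits (25 grid evaluations plus ≤3 local refines
each); the full suite runs in well under a minute and the acceptance
script in seconds. These sizes were chosen as the smallest at which the
asserted properties are stable.

## Known limitations

* Steady-state only; no transient, bifurcation or continuation analysis.
* Uniqueness of the equilibrium is an empirical assertion (see above).
* The aggregate phase has no size structure — an alternative nucleation
  mechanism (a WT–mutant oligomer growing by WT addition) is out of scope.
* The cell-population link is illustrative, not calibrated.
* The fixed turnover rates are taken as known during inference; only
  (γ, λ_agg) are fitted.
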