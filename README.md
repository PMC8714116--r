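# kerataggr

Steady-state kinetics of keratin aggregation in cells that co-express
wild-type (WT) and mutant keratin 14.

## The problem

Severe keratin-14 mutations (e.g. the R125P substitution behind
Dowling–Meara epidermolysis bullosa simplex) cause cytoplasmic keratin
aggregates — but, counter-intuitively, cell-culture experiments find the
*most* aggregates and the softest cells when the mutant protein is only
~25% of total keratin, not at 50% or 100%. `kerataggr` implements a
mass-action reaction-network model that explains this peak at low mutant
fraction through **asymmetric aggregate formation**: an aggregate-forming
encounter between one WT and one mutant particle incorporates γ units of
WT keratin per unit of mutant keratin.

The package is for systems-biology and biophysics researchers who want to
explore the model's parameter space, reproduce its regime predictions, or
test how well its two unmeasured parameters can be recovered from noisy
observations.

## The model

Each keratin species X ∈ {W, M} occupies four phases: soluble (s_X),
particulate (p_X), filamentous (f_X) and aggregate (a_X), expressed as
fractions of the constant total keratin pool K_total. In scaled time
τ = k⁻·t (k⁻ is the common depolymerization rate) the dynamics are

    ds_W/dτ = −λ_W^SP s_W + (p_W + f_W + a_W)
    ds_M/dτ = −λ_M^SP s_M + (p_M + f_M + a_M)
    dp_W/dτ = λ_W^SP s_W − p_W − λ_W^PF p_W − γ λ_agg p_W p_M
    dp_M/dτ = λ_M^SP s_M − p_M − λ_M^PF p_M − λ_agg p_W p_M
    df_W/dτ = λ_W^PF p_W − f_W
    df_M/dτ = λ_M^PF p_M − f_M
    da_W/dτ = γ λ_agg p_W p_M − a_W
    da_M/dτ = λ_agg p_W p_M − a_M

with λ = k/k⁻ for the first-order rates and λ_agg = k_agg·K_total/k⁻ for
the bimolecular aggregation step. The literature turnover rates make
mutant filament assembly 200-fold slower than WT (λ_W^PF = 100,
λ_M^PF = 0.5, λ^SP = 1 for both). Two summaries drive the analysis:

* χ_M = s_M + p_M + f_M + a_M — the total mutant fraction;
* Q = (a_W + a_M + p_W + p_M)/(f_W + f_M) — the observable aggregate
  burden: non-filamentous assembled keratin relative to the filament
  network.

The steady state is found two independent ways — stiff adaptive
integration (LSODA) until all |d/dt| < 10⁻¹⁰ s⁻¹, and an algebraic
reduction of the stationarity conditions to a single bracketed
root-finding problem — and the two routes are cross-checked throughout.

## Worked example

```r
library(kerataggr)

p <- model_params(gamma = 10, lam_agg = 1e4)   # the two free parameters
integrate_to_stationary(p, initial_state(0.25))
#> Keratin steady state (integration)
#>   converged:           TRUE
#>   chi_M:               0.25
#>   Q:                   13.0243
#>   max |d/dt| (s^-1):   1.069378e-14
#>   tau elapsed:         20
#>          s_W          s_M          p_W          p_M          f_W          f_M
#> 0.3750000000 0.1250000000 0.0000627449 0.0587558156 0.0062744898 0.0293779078
#>          a_W          a_M
#> 0.3686627653 0.0368662765
```

At a 25% mutant fraction the aggregate pools hold ~0.41 of all keratin
while filaments hold only ~0.036 — an aggregate burden Q ≈ 13, an order
of magnitude more keratin in aggregates than in filaments. Sweeping χ_M
locates the burden peak:

```r
sweep_chi(p)
#> chi_M sweep over 201 points (gamma = 10 , lam_agg = 10000 )
#>   chi_M_max: 0.1682341   Q_max: 16.62431
#>   integrator cross-check rel. discrepancy: 3.490094e-10
```

The peak sits at χ_M ≈ 17%, inside the 15–30% window where the
cell-culture data put it. With symmetric binding (γ = 1) the peak always
sits above 50% mutant — asymmetry is what moves it down. Closing the
loop, the two free parameters are recoverable from noisy synthetic data:

```r
ds <- generate_q_observations(p, noise_sigma = 0.05, n_reps = 3, seed = 1)
fit_params(ds)
#> Keratin aggregation parameter fit
#>   gamma_hat:   9.943177 (log10 0.9975252)
#>   lam_agg_hat: 10546.62 (log10 4.023113)
#>   loss:        0.2919659
#>   converged:   TRUE  (313 objective evals)
#>   axis flatness (loss variation +/- 0.1 log10): gamma 5.264789, lam_agg 0.4059887
```

`phase_map()` tiles (γ, λ_agg) space with `sweep_chi()` results and masks
the region whose peak falls in the 15–30% window; `cmd_steady()`,
`cmd_sweep()`, `cmd_phasemap()`, `cmd_simulate()` and `cmd_fit()` (and the
`inst/cli/kerataggr` Rscript wrapper) drive the same pipeline from JSON
configs and write TSV/JSON outputs.

See `vignettes/keratin-aggregation-model.Rmd` for the full account of the
model, the numerical choices and the limitations.

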