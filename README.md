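# slowbindr

Analysis of slow-binding, covalent-reversible enzyme inhibition kinetics,
built around the assay designs used to characterize peptidyl-ketoamide
inhibitors of rhomboid intramembrane proteases (GlpG-class serine
proteases with a Ser-His dyad). It is aimed at enzymologists and
medicinal chemists who measure fluorogenic progress curves and need
mechanism-level constants — kon, koff, Ki — rather than bare IC50s.

## What it computes

Slow-binding inhibitors produce biphasic progress curves described by the
integrated rate law

    [P](t) = vs·t + (vi − vs)/kobs · (1 − exp(−kobs·t))

with initial rate `vi`, steady-state rate `vs`, and onset-of-inhibition
rate constant `kobs`. The package covers the full chain:

* **Simulation** (`simulate_experiment`, `closed_form_curve`,
  `ode_curve`, `simulate_dilution`, `add_noise`): closed-form and
  brute-force ODE generation of inhibited progress curves, steady-state
  rate grids, dose-response assays and 100-fold jump dilutions, with a
  seeded Gaussian noise model (bit-reproducible via `curve_seed`).
* **Progress-curve fitting** (`fit_progress_curve`, `batch_fit`):
  nonlinear fits of the law above with curvature-aware starts, optional
  relative-error weighting, and an F-test guard that refuses to report
  `kobs` from curves indistinguishable from a straight line.
* **Rate analysis** (`fit_kobs_linear`, `fit_kobs_hyperbolic`,
  `compare_kobs_models`, `test_vi_independence`): one-step kinetics give
  `kobs = koff + kon·[I]`, so the linear regression yields kon (slope),
  koff (intercept) and the apparent inhibitory constant
  `Kiapp = koff/kon`; the hyperbolic two-step alternative is arbitrated
  by AICc.
* **Modality** (`global_fit_modality`, `ki_from_kiapp`,
  `ic50_from_scheme`): global fitting of vs over a substrate × inhibitor
  grid to the competitive / noncompetitive / uncompetitive / mixed
  models, AICc selection, and conversion of Kiapp to the true Ki (for
  noncompetitive inhibition, α = 1, they are identical).
* **Dose-response and screening** (`fit_ic50`, `conversion_from_bands`,
  `correct_background`, `abp_percent_inhibition`): four-parameter
  logistic IC50s with first-class "beyond tested range" results, in vivo
  conversion from immunoblot band tables with knockout background
  subtraction, and activity-based-probe percent inhibition.
* **Reversibility** (`analyze_dilution`): jump-dilution classification
  (reversible / irreversible / ambiguous) with the model expectation
  `Kiapp/(Kiapp + I_diluted)` for the recovered activity fraction.
* **I/O and pipeline** (`read_progress_curves`, `write_progress_curves`,
  `experiment_config`, `run_pipeline`): long-format CSV curves, YAML
  configs with lossless round-trips, and a deterministic end-to-end
  pipeline report with config-hash provenance.

Published reference constants of the lead compounds are available as
`ketoamide_constants()`, `truncation_series_ic50()` and
`warhead_screen_ic50()`.

## Worked example

Simulate the lead-compound progress-curve assay (0.5 nM enzyme, 25 uM
substrate, 1:3 inhibitor series from 1,333 nM, 2 h) from its published
constants (Kiapp = 123 nM, koff = 4.2e-3 min⁻¹), add 2% relative noise,
and recover Kiapp through the fitting pipeline:

```r
library(slowbindr)

scheme <- kinetic_scheme("noncompetitive", Ki = 123, koff = 4.2e-3,
                         Km = 10, kcat = 2)
design <- assay_design(E0 = 0.5, S0 = 25,
                       I_grid = c(0, 1333 / 3^(6:0)),
                       t_grid = seq(0, 120, 2))
kiapp <- sapply(1:25, function(s) {
  nm <- noise_model(sigma_rel = 0.02, seed = curve_seed(1, paste0("rep_", s)))
  fam <- simulate_experiment(scheme, design, noise = nm)
  prof <- batch_fit(fam, weighting = "relative", fix_offset = TRUE)
  suppressWarnings(fit_kobs_linear(prof, weighted = TRUE))$Kiapp
})
median(kiapp)
#> [1] 131.3906
```

The replicate median lands on the generating value (123 nM) well inside
its experimental uncertainty (±47 nM); a single 8-curve experiment is
only good to a factor of ~2 at this noise level, which is why medians
over replicates are reported. Modality selection on a noisy steady-state
grid (compound 11, Ki = 45 nM, 3% noise):

```r
sc <- kinetic_scheme("noncompetitive", Ki = 45, koff = 3.9e-3, Km = 5, kcat = 2)
g  <- expand.grid(substrate_uM = c(1.25, 2.5, 5, 10, 20, 40),
                  inhibitor_nM = c(0, 20, 60, 180))
set.seed(7)
v  <- pmax(steady_rate(sc, g$substrate_uM, g$inhibitor_nM, 1) *
           (1 + rnorm(24, 0, 0.03)), 0)
global_fit_modality(michaelis_grid(g$substrate_uM, g$inhibitor_nM, v,
                                   enzyme_nM = 1))
#> Inhibition modality selection (global Michaelis fit)
#>           model       aicc selected
#>     competitive  -89.54832
#>  noncompetitive -163.82553      <--
#>   uncompetitive -121.70888
#>           mixed -160.61771
#>   selected: noncompetitive | Ki = 48.8364 nM, Km = 4.95976 uM, Vmax = 1.96712
#>   note: mixed-model alpha CI covers 1: consistent with noncompetitive
```

The AICc table ranks the four global fits; the noncompetitive model wins
and its Ki (48.8 nM here) estimates the true inhibitory constant.

See `vignettes/slow-binding-kinetics.Rmd` for the models, estimator
choices and their rationale.

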