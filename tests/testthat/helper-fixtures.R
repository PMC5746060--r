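# shared fixture builders: schemes and designs used across the suite,
# parameterized by the published constants of the lead ketoamides

scheme_compound10 <- function(Km = 10, kcat = 2)
  kinetic_scheme("noncompetitive", Ki = 123, koff = 4.2e-3,
                 Km = Km, kcat = kcat)

scheme_compound11 <- function(Km = 5, kcat = 2)
  kinetic_scheme("noncompetitive", Ki = 45, koff = 3.9e-3,
                 Km = Km, kcat = kcat)

# progress-curve assay: 0.5 nM enzyme, 25 uM substrate, 1:3 inhibitor
# dilution series from 1333 nM plus the uninhibited control, 2 h at 2 min
design_progress <- function(dt = 2, t_end = 120)
  assay_design(E0 = 0.5, S0 = 25,
               I_grid = c(0, 1333 / 3^(6:0)),
               t_grid = seq(0, t_end, by = dt))

# steady-state grid: 6 substrate levels bracketing Km, 4 inhibitor levels
michaelis_design <- function() {
  list(substrate_uM = c(1.25, 2.5, 5, 10, 20, 40),
       inhibitor_nM = c(0, 20, 60, 180), enzyme_nM = 1)
}

simulate_michaelis_grid <- function(scheme, sigma_rel = 0, seed = 1L,
                                    md = michaelis_design()) {
  g <- expand.grid(substrate_uM = md$substrate_uM,
                   inhibitor_nM = md$inhibitor_nM)
  v <- steady_rate(scheme, g$substrate_uM, g$inhibitor_nM, md$enzyme_nM)
  if (sigma_rel > 0) {
    set.seed(seed)
    v <- pmax(v * (1 + rnorm(length(v), 0, sigma_rel)), 0)
  }
  michaelis_grid(g$substrate_uM, g$inhibitor_nM, v,
                 enzyme_nM = md$enzyme_nM)
}

# a synthetic biphasic curve built directly from the integrated rate law,
# bypassing the scheme layer (for exact-recovery tests of the fitter)
make_biphasic_curve <- function(vi, vs, kobs, t = seq(0, 120, by = 2),
                                offset = 0, I = 100) {
  P <- vs * t + (vi - vs) / kobs * (1 - exp(-kobs * t))
  progress_curve(t, offset + P, inhibitor_nM = I, substrate_uM = 25,
                 enzyme_nM = 0.5, curve_id = sprintf("synthetic_I%g", I))
}
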