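#' Define a mechanistic inhibition scheme
#'
#' A `kinetic_scheme` is the ground truth used by the simulators and the
#' reference against which the fitting pipeline is validated. It describes a
#' Michaelis-Menten enzyme (`kcat`, `Km`) inhibited by a slow-binding,
#' reversible inhibitor characterized by its true inhibitory constant `Ki`
#' and dissociation rate constant `koff`; the association rate constant is
#' derived as `kon = koff / Ki` unless overridden. The inhibition modality
#' (competitive, noncompetitive, uncompetitive or mixed) determines how the
#' inhibitor partitions between the free enzyme E and the enzyme-substrate
#' complex ES: the inhibitor binds E with dissociation constant `Ki` and ES
#' with `alpha * Ki`. Pure noncompetitive inhibition is the special case
#' `alpha = 1` (equal affinity for both forms); competitive corresponds to
#' `alpha = Inf` (no binding to ES) and uncompetitive to binding ES only.
#'
#' Optionally the scheme can carry a second, slow isomerization step
#' (E + I <-> EI <-> EI*) with forward rate `k5`, reverse rate `k6` and
#' initial-complex dissociation constant `Ki1`, giving the saturating
#' (hyperbolic) kobs-vs-inhibitor dependence diagnostic of two-step binding.
#'
#' Units are fixed throughout the package: time in minutes, inhibitor and
#' enzyme concentrations in nM, substrate concentrations in uM, first-order
#' rates in min^-1, `kon` in nM^-1 min^-1.
#'
#' @param modality one of `"competitive"`, `"noncompetitive"`,
#'   `"uncompetitive"`, `"mixed"`.
#' @param Ki true inhibitory constant (nM), dissociation constant of the
#'   inhibitor from the free enzyme (from ES for uncompetitive).
#' @param koff dissociation rate constant (min^-1).
#' @param kon association rate constant (nM^-1 min^-1); defaults to
#'   `koff / Ki`.
#' @param alpha ratio of the ES-bound to E-bound dissociation constants;
#'   only meaningful for `modality = "mixed"`. Fixed to 1 for
#'   noncompetitive, ignored (infinite) for competitive and (ES-only) for
#'   uncompetitive.
#' @param Km Michaelis constant of the substrate (uM).
#' @param kcat turnover number (min^-1).
#' @param two_step if `TRUE` the scheme includes the EI <-> EI*
#'   isomerization and `k5`, `k6`, `Ki1` must be supplied.
#' @param k5,k6 forward and reverse isomerization rate constants (min^-1).
#' @param Ki1 dissociation constant of the initial encounter complex (nM).
#'
#' @return an object of class `kinetic_scheme`.
#' @examples
#' # one-step noncompetitive scheme with Ki = 120 nM, koff = 4.2e-3 min^-1
#' sc <- kinetic_scheme("noncompetitive", Ki = 120, koff = 4.2e-3,
#'                      Km = 10, kcat = 2)
#' sc$kon  # koff / Ki
#' @export
kinetic_scheme <- function(modality = c("noncompetitive", "competitive",
                                        "uncompetitive", "mixed"),
                           Ki, koff, kon = NULL, alpha = 1,
                           Km, kcat,
                           two_step = FALSE, k5 = NULL, k6 = NULL,
                           Ki1 = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.numeric(Ki), length(Ki) == 1L, is.finite(Ki),
            is.numeric(koff), length(koff) == 1L, is.finite(koff),
            is.numeric(Km), length(Km) == 1L,
            is.numeric(kcat), length(kcat) == 1L)
  if (Ki <= 0) stop("'Ki' must be > 0")
  if (koff < 0) stop("'koff' must be >= 0")
  if (Km <= 0) stop("'Km' must be > 0")
  if (kcat <= 0) stop("'kcat' must be > 0")
  if (is.null(kon)) kon <- koff / Ki
  if (kon < 0) stop("'kon' must be >= 0")
  if (modality == "noncompetitive") {
    alpha <- 1
  } else if (modality == "mixed") {
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
      stop("mixed modality requires a finite 'alpha' > 0")
  }
  if (two_step) {
    if (is.null(k5) || is.null(k6) || is.null(Ki1))
      stop("two_step = TRUE requires 'k5', 'k6' and 'Ki1'")
    if (k5 < 0 || k6 < 0 || Ki1 <= 0)
      stop("'k5', 'k6' must be >= 0 and 'Ki1' > 0")
  } else {
    if (!is.null(k5) || !is.null(k6) || !is.null(Ki1))
      stop("'k5', 'k6', 'Ki1' are only meaningful when two_step = TRUE")
  }
  structure(
    list(modality = modality, Ki = Ki, koff = koff, kon = kon,
         alpha = alpha, Km = Km, kcat = kcat, two_step = two_step,
         k5 = k5, k6 = k6, Ki1 = Ki1),
    class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme:", x$modality,
      if (x$two_step) "(two-step binding)" else "(one-step binding)", "\n")
  cat(sprintf("  Ki   = %g nM   koff = %g min^-1   kon = %g nM^-1 min^-1\n",
              x$Ki, x$koff, x$kon))
  if (x$modality == "mixed")
    cat(sprintf("  alpha = %g\n", x$alpha))
  cat(sprintf("  Km   = %g uM   kcat = %g min^-1\n", x$Km, x$kcat))
  if (x$two_step)
    cat(sprintf("  k5 = %g min^-1   k6 = %g min^-1   Ki1 = %g nM\n",
                x$k5, x$k6, x$Ki1))
  invisible(x)
}

#' Define an assay design
#'
#' Concentrations and sampling times of a progress-curve experiment. The
#' fluorescence readout is modelled as
#' `signal = baseline + gain * [P]` with product `[P]` in uM.
#'
#' @param E0 enzyme concentration (nM).
#' @param S0 substrate concentration (uM).
#' @param I_grid inhibitor concentrations (nM); include 0 for designs that
#'   normalize to the uninhibited rate.
#' @param t_grid sampling times (min), strictly increasing, starting at 0.
#' @param preincubation_min duration of enzyme + inhibitor incubation before
#'   substrate addition (min).
#' @param gain signal per product (AU uM^-1).
#' @param baseline signal offset (AU).
#' @return an object of class `assay_design`.
#' @export
assay_design <- function(E0, S0, I_grid, t_grid,
                         preincubation_min = 0, gain = 1000, baseline = 0) {
  stopifnot(is.numeric(E0), E0 > 0, is.numeric(S0), S0 > 0,
            is.numeric(gain), gain > 0,
            is.numeric(preincubation_min), preincubation_min >= 0,
            is.numeric(I_grid), length(I_grid) >= 1L,
            is.numeric(t_grid), length(t_grid) >= 2L)
  if (any(I_grid < 0)) stop("inhibitor concentrations must be >= 0")
  if (t_grid[1] != 0) stop("'t_grid' must start at 0")
  if (any(diff(t_grid) <= 0)) stop("'t_grid' must be strictly increasing")
  structure(
    list(E0 = E0, S0 = S0, I_grid = I_grid, t_grid = t_grid,
         preincubation_min = preincubation_min,
         gain = gain, baseline = baseline),
    class = "assay_design")
}

#' Define a measurement-noise model
#'
#' Gaussian noise applied as `signal * (1 + eps_rel) + eps_abs` with
#' `eps_rel ~ N(0, sigma_rel^2)` and `eps_abs ~ N(0, sigma_abs^2)`.
#' Per-curve random streams are derived deterministically from `seed` and
#' the curve id (see [add_noise()]), so a whole simulated experiment is
#' bit-reproducible.
#'
#' @param sigma_rel relative noise SD (dimensionless).
#' @param sigma_abs absolute noise SD (AU).
#' @param seed master integer seed.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sigma_rel = 0, sigma_abs = 0, seed = 1L) {
  stopifnot(is.numeric(sigma_rel), sigma_rel >= 0,
            is.numeric(sigma_abs), sigma_abs >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(sigma_rel = sigma_rel, sigma_abs = sigma_abs,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# modality-specific denominator of the inhibited Michaelis rate law:
# Km*(1 + I/Ki) + S*(1 + I/(alpha*Ki)), with competitive = no ES binding
# and uncompetitive = no E binding.
inhibition_denominator <- function(scheme, S, I) {
  Ki <- scheme$Ki
  switch(scheme$modality,
         competitive    = scheme$Km * (1 + I / Ki) + S,
         noncompetitive = scheme$Km * (1 + I / Ki) + S * (1 + I / Ki),
         uncompetitive  = scheme$Km + S * (1 + I / Ki),
         mixed          = scheme$Km * (1 + I / Ki) +
                          S * (1 + I / (scheme$alpha * Ki)))
}

#' Steady-state inhibited rate
#'
#' Evaluates the steady-state rate of product formation
#' `v = kcat * E0 * S / denom`, where the denominator carries the
#' modality-specific inhibition terms:
#' competitive `Km (1 + I/Ki) + S`, noncompetitive
#' `(Km + S)(1 + I/Ki)`, uncompetitive `Km + S (1 + I/Ki)`, and mixed
#' `Km (1 + I/Ki) + S (1 + I/(alpha Ki))`.
#'
#' @param scheme a [kinetic_scheme()].
#' @param S substrate concentration (uM); vectorized.
#' @param I inhibitor concentration (nM); vectorized.
#' @param E0 enzyme concentration (nM).
#' @return rate of product formation in nM min^-1 (i.e. `kcat * E0` at
#'   saturation and `I = 0`).
#' @export
steady_rate <- function(scheme, S, I, E0) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (any(S < 0)) stop("substrate concentration must be >= 0")
  if (any(I < 0)) stop("inhibitor concentration must be >= 0")
  if (any(E0 < 0)) stop("enzyme concentration must be >= 0")
  scheme$kcat * E0 * S / inhibition_denominator(scheme, S, I)
}

# effective second-order association rate constant at substrate S: the
# inhibitor sees the E/ES pool partitioned by rapid substrate equilibrium,
# binding E at kon and ES at kon/alpha (competitive: alpha -> Inf;
# uncompetitive: E-binding absent).
kon_effective <- function(scheme, S) {
  fE  <- scheme$Km / (scheme$Km + S)
  fES <- S / (scheme$Km + S)
  switch(scheme$modality,
         competitive    = scheme$kon * fE,
         noncompetitive = scheme$kon,
         uncompetitive  = scheme$kon * fES,
         mixed          = scheme$kon * (fE + fES / scheme$alpha))
}

#' Predicted onset-of-inhibition rate constant kobs
#'
#' For one-step slow binding the observed rate constant of the approach to
#' the inhibited steady state is affine in inhibitor concentration,
#' `kobs = koff + kon_eff * I`, where `kon_eff` is the association rate
#' constant attenuated by substrate competition:
#' `kon / (1 + S/Km)` for competitive, `kon` for noncompetitive
#' (equal on-rates to E and ES, alpha = 1), `kon / (1 + Km/S)` for
#' uncompetitive, and the fraction-weighted combination for mixed. For a
#' two-step scheme (E + I <-> EI <-> EI*) the dependence saturates:
#' `kobs = k6 + k5 * I / (Ki1_eff + I)` with `Ki1_eff` the substrate-
#' corrected encounter-complex constant.
#'
#' @inheritParams steady_rate
#' @return kobs in min^-1; vectorized over `I`.
#' @export
kobs_predict <- function(scheme, S, I) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (any(S < 0) || any(I < 0)) stop("concentrations must be >= 0")
  if (scheme$two_step) {
    Ki1_eff <- scheme$Ki1 * scheme$kon / kon_effective(scheme, S)
    scheme$k6 + scheme$k5 * I / (Ki1_eff + I)
  } else {
    scheme$koff + kon_effective(scheme, S) * I
  }
}

#' Apparent inhibitory constant implied by a scheme at given substrate
#'
#' `Kiapp = koff / kon_eff(S)`: the inhibition constant uncorrected for
#' modality and substrate. Equals the true `Ki` for pure noncompetitive
#' inhibition; `Ki (1 + S/Km)` for competitive; `Ki (1 + Km/S)` for
#' uncompetitive.
#'
#' @inheritParams steady_rate
#' @return Kiapp in nM.
#' @export
kiapp_from_scheme <- function(scheme, S) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  scheme$koff / kon_effective(scheme, S)
}
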