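#' Fit a four-parameter logistic dose-response curve
#'
#' Apparent-IC50 determination by nonlinear fit of
#' `y = bottom + (top - bottom) / (1 + (x / IC50)^h)`
#' to a (concentration, response) table, with the IC50 parameterized on the
#' log scale. The Hill slope `h` is free by default; `bottom` and/or `top`
#' can be fixed (e.g. 0 and 100 for percent-activity data). Vehicle
#' (zero-concentration) rows anchor `top` through the fixed/fitted plateau
#' but are excluded from the log-concentration axis.
#'
#' If the responses never leave the plateaus -- all within `bracket_tol`
#' (fractional) of `top` or of `bottom` -- the transition is not bracketed
#' and no numeric IC50 is reported: the fit is flagged
#' `"IC50 > max tested"` (or `"< min tested"`), the same first-class
#' out-of-range result as an assay reported as, say, "IC50 higher than
#' 1 mM".
#'
#' @param conc inhibitor concentrations (any single unit, recorded in
#'   `unit`).
#' @param response measured responses (activity, conversion, ...).
#' @param fix_bottom,fix_top optional fixed plateau values.
#' @param fix_hill optional fixed Hill slope (e.g. 1).
#' @param unit concentration unit label carried through to the result.
#' @param bracket_tol fraction of the top-bottom span within which all
#'   responses must stay near one plateau for the curve to be declared
#'   out of range.
#' @return an object of class `dose_response_fit` with `ic50`, `hill`,
#'   `top`, `bottom`, `se`, `rss`, `converged`, `out_of_range`
#'   (`NA`, `"above"` or `"below"`), `unit`.
#' @export
fit_ic50 <- function(conc, response, fix_bottom = NULL, fix_top = NULL,
                     fix_hill = NULL, unit = "nM", bracket_tol = 0.15) {
  stopifnot(length(conc) == length(response), all(conc >= 0),
            all(is.finite(response)))
  pos <- conc > 0
  if (sum(pos) < 5L)
    stop("need >= 5 nonzero concentrations spanning the transition")

  top0 <- if (!is.null(fix_top)) fix_top else
    mean(response[conc <= stats::quantile(conc[pos], 0.25) | !pos])
  bot0 <- if (!is.null(fix_bottom)) fix_bottom else min(response)
  # reference scale for the bracketing check: the top plateau (responses
  # are activities/conversions, so the floor of a full transition is ~0)
  span <- max(abs(top0), .Machine$double.eps)

  out <- list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
              bottom = NA_real_,
              se = c(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                     bottom = NA_real_),
              rss = NA_real_, converged = FALSE, out_of_range = NA_character_,
              unit = unit, n = length(conc))
  class(out) <- "dose_response_fit"

  # transition bracketed? all responses stuck at one plateau -> flag
  if (all(response >= top0 - bracket_tol * span)) {
    out$out_of_range <- "above"   # IC50 > max tested concentration
    out$top <- top0
    return(out)
  }
  if (all(response <= bot0 + bracket_tol * span)) {
    out$out_of_range <- "below"
    out$bottom <- bot0
    return(out)
  }

  d <- data.frame(x = conc[pos], y = response[pos])
  # crude start for IC50: concentration closest to the half response
  half <- (top0 + bot0) / 2
  ic50_0 <- d$x[which.min(abs(d$y - half))]
  start <- list(log10_ic50 = log10(ic50_0))
  if (is.null(fix_hill)) start$hill <- 1
  if (is.null(fix_top)) start$top <- top0
  if (is.null(fix_bottom)) start$bottom <- bot0

  model_y <- function(x, log10_ic50, hill, top, bottom)
    bottom + (top - bottom) / (1 + (x / 10^log10_ic50)^hill)
  # splice fixed parameters into the model formula as constants
  fml <- stats::as.formula(bquote(
    y ~ model_y(x, log10_ic50,
                .(if (is.null(fix_hill)) quote(hill) else fix_hill),
                .(if (is.null(fix_top)) quote(top) else fix_top),
                .(if (is.null(fix_bottom)) quote(bottom) else fix_bottom))),
    env = environment())
  lower <- c(log10_ic50 = -12, hill = 0.05, top = -Inf, bottom = -Inf)
  upper <- c(log10_ic50 = 12, hill = 20, top = Inf, bottom = Inf)
  do_fit <- function(ctrl) tryCatch(
    minpack.lm::nlsLM(fml, data = d, start = start,
                      lower = lower[names(start)],
                      upper = upper[names(start)], control = ctrl),
    error = function(e) e)
  fit <- do_fit(minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-14, ptol = 1e-14))
  # exact-fit data can defeat the model construction at very tight
  # tolerances; the default convergence control is then sufficient
  if (inherits(fit, "error"))
    fit <- do_fit(minpack.lm::nls.lm.control(maxiter = 500))
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(out)
  }
  cf <- stats::coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) stats::setNames(
                    rep(NA_real_, length(cf)), names(cf)))
  out$converged <- TRUE
  out$ic50 <- 10^unname(cf["log10_ic50"])
  out$hill <- if (is.null(fix_hill)) unname(cf["hill"]) else fix_hill
  out$top <- if (is.null(fix_top)) unname(cf["top"]) else fix_top
  out$bottom <- if (is.null(fix_bottom)) unname(cf["bottom"]) else
    fix_bottom
  # SE of IC50 from SE of log10(IC50): delta method
  out$se <- c(ic50 = out$ic50 * log(10) * unname(ses["log10_ic50"]),
              hill = if (is.null(fix_hill)) unname(ses["hill"]) else 0,
              top = if (is.null(fix_top)) unname(ses["top"]) else 0,
              bottom = if (is.null(fix_bottom)) unname(ses["bottom"])
                       else 0)
  out$rss <- sum(stats::residuals(fit)^2)
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Dose-response (4PL) fit\n")
  if (!is.na(x$out_of_range)) {
    cat("  IC50", if (x$out_of_range == "above") "> max" else "< min",
        "tested concentration (transition not bracketed)\n")
  } else if (!x$converged) {
    cat("  NOT CONVERGED\n")
  } else {
    cat(sprintf("  IC50 = %g +/- %g %s | Hill = %g | top = %g, bottom = %g\n",
                x$ic50, x$se[["ic50"]], x$unit, x$hill, x$top, x$bottom))
  }
  invisible(x)
}

#' Build a band-intensity table for conversion assays
#'
#' Lane-wise substrate and product band intensities from gel/immunoblot
#' quantification, keyed by condition label and inhibitor concentration.
#'
#' @param condition character lane labels ("DMSO"/"vehicle" for the
#'   uninhibited control).
#' @param inhibitor concentration per lane (unit free, recorded upstream).
#' @param substrate_au,product_au band intensities (AU, >= 0).
#' @return an object of class `band_table` (a data.frame).
#' @export
band_table <- function(condition, inhibitor, substrate_au, product_au) {
  stopifnot(length(condition) == length(inhibitor),
            length(substrate_au) == length(condition),
            length(product_au) == length(condition))
  if (any(substrate_au < 0) || any(product_au < 0))
    stop("band intensities must be >= 0")
  d <- data.frame(condition = as.character(condition),
                  inhibitor = inhibitor,
                  substrate_au = substrate_au, product_au = product_au,
                  stringsAsFactors = FALSE)
  class(d) <- c("band_table", "data.frame")
  d
}

#' Substrate conversion from band intensities
#'
#' Per lane, `conversion = product / (product + substrate)`; conversions
#' are then normalized to the vehicle-control lane (which defines 100%),
#' yielding the relative-conversion dose-response used for in vivo IC50
#' determination. Lanes with zero total intensity are excluded with a
#' warning.
#'
#' @param bands a [band_table()].
#' @param vehicle condition label of the uninhibited control lane.
#' @return a data.frame with columns `condition`, `inhibitor`,
#'   `conversion` (raw fraction) and `response` (percent of vehicle
#'   conversion), suitable for [fit_ic50()].
#' @export
conversion_from_bands <- function(bands, vehicle = "DMSO") {
  stopifnot(inherits(bands, "band_table"))
  if (!any(bands$condition == vehicle))
    stop("vehicle lane '", vehicle, "' not found")
  total <- bands$substrate_au + bands$product_au
  bad <- total == 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " lane(s) with zero total intensity: ",
            paste(bands$condition[bad], collapse = ", "))
    bands <- bands[!bad, , drop = FALSE]
    total <- total[!bad]
  }
  conv <- bands$product_au / total
  v_conv <- mean(conv[bands$condition == vehicle])
  if (v_conv == 0) stop("vehicle conversion is zero; cannot normalize")
  data.frame(condition = bands$condition, inhibitor = bands$inhibitor,
             conversion = conv, response = 100 * conv / v_conv,
             stringsAsFactors = FALSE)
}

#' Knockout-background correction of product band intensities
#'
#' When the specific cleavage product co-migrates with nonspecific bands,
#' the product-region intensity measured in protease-knockout control
#' lanes (same inhibitor concentration) is subtracted:
#' `corrected = max(0, observed - knockout)`. The applied correction per
#' lane is recorded in the `correction` attribute; a knockout intensity
#' at or above the observed one clamps the corrected product to 0 with a
#' warning.
#'
#' @param bands a [band_table()] of the protease-positive lanes.
#' @param knockout a [band_table()] of the knockout lanes, matched to
#'   `bands` by inhibitor concentration.
#' @return the corrected [band_table()] with attribute `correction`.
#' @export
correct_background <- function(bands, knockout) {
  stopifnot(inherits(bands, "band_table"), inherits(knockout, "band_table"))
  idx <- match(bands$inhibitor, knockout$inhibitor)
  if (anyNA(idx))
    stop("no knockout lane matches inhibitor concentration(s): ",
         paste(unique(bands$inhibitor[is.na(idx)]), collapse = ", "))
  ko <- knockout$product_au[idx]
  corrected <- bands$product_au - ko
  clamped <- corrected < 0
  if (any(clamped))
    warning(sum(clamped), " lane(s) had knockout intensity >= observed; ",
            "corrected product clamped to 0")
  bands$product_au <- pmax(corrected, 0)
  attr(bands, "correction") <- ko
  bands
}

#' Percent inhibition from activity-based-probe competition
#'
#' Residual labeling of the active enzyme by an activity-based probe after
#' inhibitor treatment, normalized to the DMSO-treated control
#' (100% activity): `percent inhibition = 100 * (1 - band / dmso_band)`,
#' clamped to `[0, 100]`. Vectorized, so a matrix of band intensities over
#' (compound, concentration, enzyme) with a matching DMSO-control matrix
#' yields the heatmap-style selectivity table directly.
#'
#' @param band treated-lane intensity (AU), vector or matrix.
#' @param dmso_band matched DMSO-control intensity (AU), > 0; recycled.
#' @return percent inhibition in `[0, 100]`, same shape as `band`.
#' @export
abp_percent_inhibition <- function(band, dmso_band) {
  if (any(dmso_band <= 0)) stop("'dmso_band' must be > 0")
  if (any(band < 0)) stop("band intensities must be >= 0")
  pmin(pmax(100 * (1 - band / dmso_band), 0), 100)
}
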