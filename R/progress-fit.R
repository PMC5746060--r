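#' Fit the slow-binding rate law to a single progress curve
#'
#' Nonlinear least-squares fit of
#' `signal(t) = offset + vs t + (vi - vs)/kobs * (1 - exp(-kobs t))`
#' to a biphasic progress curve, yielding the initial rate `vi`, the
#' steady-state rate `vs` (both in AU min^-1, i.e. on the signal scale) and
#' the onset-of-inhibition rate constant `kobs` (min^-1), with asymptotic
#' standard errors from the local curvature of the objective.
#'
#' Starting values follow curvature-aware heuristics: `vi` from the OLS
#' slope of the first 15% of points, `vs` from the last 25%, and `kobs`
#' from `3 / t_mid`, where `t_mid` is the time at which half of the excess
#' of the signal over the terminal `vs` line has decayed; `kobs` is bounded
#' to `(1e-5, 100)` min^-1.
#'
#' A curve statistically indistinguishable from a straight line carries no
#' information on `kobs`: an extra-sum-of-squares F-test of the full model
#' against the nested straight line (`offset + v t`) decides at level
#' `alpha` whether curvature is detectable. When it is not, the result is
#' flagged `linear = TRUE`, `kobs` is `NA`, and `vi`/`vs` are both set to
#' the straight-line slope.
#'
#' @param curve a [progress_curve()].
#' @param fix_offset if `TRUE` the baseline offset is fixed to 0 instead of
#'   fitted (useful for synthetic data with a known zero baseline).
#' @param alpha significance level of the linearity F-test.
#' @param weighting `"none"` for ordinary least squares (the default,
#'   mirroring common curve-fitting practice) or `"relative"` for weights
#'   `1/max(|y|, 0.05 max|y|)^2`, the approximate inverse-variance scheme
#'   when measurement error is proportional to the signal -- fluorimeter
#'   noise typically is, and the scheme makes the precise early points of
#'   a progress curve count accordingly.
#' @param weights optional explicit per-point weights, overriding
#'   `weighting`.
#' @return an object of class `progress_fit`: a list with `vi`, `vs`,
#'   `kobs`, `offset`, their standard errors (`se`, a named vector), `rss`,
#'   `converged`, `linear`, `n_points`, `inhibitor_nM`, `curve_id`.
#' @export
fit_progress_curve <- function(curve, fix_offset = FALSE, alpha = 0.05,
                               weighting = c("none", "relative"),
                               weights = NULL) {
  stopifnot(inherits(curve, "progress_curve"))
  weighting <- match.arg(weighting)
  t <- curve$time_min
  y <- curve$signal_au
  n <- length(t)
  if (n < 6L) stop("need at least 6 time points to fit the biphasic model")
  if (is.null(weights))
    weights <- if (weighting == "relative")
      1 / pmax(abs(y), 0.05 * max(abs(y)))^2
    else rep(1, n)

  # straight-line nested model (always needed for the linearity guard)
  lin <- stats::lm(y ~ t, weights = weights)
  rss_lin <- sum(weights * stats::residuals(lin)^2)

  start <- .progress_start(t, y)
  fml <- if (fix_offset)
    y ~ vs * t + (vi - vs) / kobs * (1 - exp(-kobs * t))
  else
    y ~ offset + vs * t + (vi - vs) / kobs * (1 - exp(-kobs * t))
  if (fix_offset) start$offset <- NULL
  lower <- c(vi = -Inf, vs = -Inf, kobs = 1e-5,
             if (!fix_offset) c(offset = -Inf))
  upper <- c(vi = Inf, vs = Inf, kobs = 100,
             if (!fix_offset) c(offset = Inf))

  do_fit <- function(ctrl) tryCatch(
    minpack.lm::nlsLM(fml, start = start, weights = weights,
                      lower = lower[names(start)],
                      upper = upper[names(start)], control = ctrl),
    error = function(e) e)
  fit <- do_fit(minpack.lm::nls.lm.control(maxiter = 200,
                                           ftol = 1e-14, ptol = 1e-14))
  if (inherits(fit, "error"))    # exact-fit degeneracy at tight tolerances
    fit <- do_fit(minpack.lm::nls.lm.control(maxiter = 200))

  out <- list(vi = NA_real_, vs = NA_real_, kobs = NA_real_,
              offset = if (fix_offset) 0 else NA_real_,
              se = c(vi = NA_real_, vs = NA_real_, kobs = NA_real_,
                     offset = NA_real_),
              rss = NA_real_, converged = FALSE, linear = FALSE,
              f_p_value = NA_real_, n_points = n,
              inhibitor_nM = curve$inhibitor_nM, curve_id = curve$curve_id)
  class(out) <- "progress_fit"

  if (inherits(fit, "error")) {
    # the biphasic model contains the straight line as a degenerate limit
    # (vi = vs), where the gradient is singular; an optimizer failure on
    # data the line explains is the linear case, anything else is genuine
    # non-convergence
    r2_lin <- 1 - rss_lin / max(sum(weights * (y - mean(y))^2),
                                .Machine$double.eps)
    if (r2_lin > 0.999) {
      slope <- unname(stats::coef(lin)[2])
      se_lin <- suppressWarnings(summary(lin)$coefficients[, "Std. Error"])
      out$converged <- TRUE
      out$linear <- TRUE
      out$vi <- out$vs <- slope
      out$offset <- if (fix_offset) 0 else unname(stats::coef(lin)[1])
      out$se <- c(vi = unname(se_lin[2]), vs = unname(se_lin[2]),
                  kobs = NA_real_,
                  offset = if (fix_offset) 0 else unname(se_lin[1]))
      out$rss <- rss_lin
      return(out)
    }
    out$message <- conditionMessage(fit)
    return(out)
  }

  cf <- stats::coef(fit)
  rss_full <- sum(weights * stats::residuals(fit)^2)
  p_full <- length(cf) ; p_lin <- 2L
  df2 <- n - p_full
  f_p <- if (df2 > 0 && rss_full < rss_lin) {
    Fstat <- ((rss_lin - rss_full) / (p_full - p_lin)) / (rss_full / df2)
    stats::pf(Fstat, p_full - p_lin, df2, lower.tail = FALSE)
  } else 1

  out$converged <- TRUE
  out$rss <- rss_full
  out$f_p_value <- f_p
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) stats::setNames(
                    rep(NA_real_, length(cf)), names(cf)))

  if (f_p > alpha) {
    # no detectable curvature: kobs is not reportable
    slope <- unname(stats::coef(lin)[2])
    out$linear <- TRUE
    out$vi <- out$vs <- slope
    out$offset <- if (fix_offset) 0 else unname(stats::coef(lin)[1])
    se_lin <- suppressWarnings(summary(lin))$coefficients[, "Std. Error"]
    out$se <- c(vi = unname(se_lin[2]), vs = unname(se_lin[2]),
                kobs = NA_real_,
                offset = if (fix_offset) 0 else unname(se_lin[1]))
    out$rss <- rss_lin
    return(out)
  }

  out$vi <- unname(cf["vi"]); out$vs <- unname(cf["vs"])
  out$kobs <- unname(cf["kobs"])
  out$offset <- if (fix_offset) 0 else unname(cf["offset"])
  out$se <- c(vi = unname(ses["vi"]), vs = unname(ses["vs"]),
              kobs = unname(ses["kobs"]),
              offset = if (fix_offset) 0 else unname(ses["offset"]))
  out
}

# curvature-aware starting values for the biphasic fit
.progress_start <- function(t, y) {
  n <- length(t)
  i_head <- seq_len(max(3L, ceiling(0.15 * n)))
  i_tail <- seq.int(n - max(3L, ceiling(0.25 * n)) + 1L, n)
  vi0 <- unname(stats::coef(stats::lm(y[i_head] ~ t[i_head]))[2])
  tail_fit <- stats::lm(y[i_tail] ~ t[i_tail])
  vs0 <- unname(stats::coef(tail_fit)[2])
  # excess of the signal over the extrapolated terminal line decays ~exp(-kobs t)
  excess <- y - (stats::coef(tail_fit)[1] + vs0 * t)
  total <- excess[1] - excess[n]
  t_mid <- if (is.finite(total) && abs(total) > 0) {
    half <- excess[1] - total / 2
    idx <- which(sign(excess - half) != sign(excess[1] - half))[1]
    if (is.na(idx)) t[ceiling(n / 2)] else t[idx]
  } else t[ceiling(n / 2)]
  kobs0 <- min(max(3 / max(t_mid, t[2]), 1e-4), 50)
  if (!is.finite(vi0)) vi0 <- vs0
  list(vi = vi0, vs = vs0, kobs = kobs0, offset = y[1])
}

#' @export
print.progress_fit <- function(x, ...) {
  cat(sprintf("Progress-curve fit '%s' ([I] = %g nM, n = %d)\n",
              x$curve_id, x$inhibitor_nM, x$n_points))
  if (!x$converged) {
    cat("  NOT CONVERGED", if (!is.null(x$message)) paste0(": ", x$message),
        "\n")
  } else if (x$linear) {
    cat(sprintf("  no detectable curvature (F-test p = %.3g); slope = %g AU/min\n",
                x$f_p_value, x$vi))
  } else {
    cat(sprintf("  vi = %g +/- %g AU/min\n  vs = %g +/- %g AU/min\n",
                x$vi, x$se[["vi"]], x$vs, x$se[["vs"]]))
    cat(sprintf("  kobs = %g +/- %g min^-1\n", x$kobs, x$se[["kobs"]]))
  }
  invisible(x)
}

#' Ordinary least-squares rate of a (near-)linear progress curve
#'
#' @param curve a [progress_curve()].
#' @return a list with `rate` (AU min^-1), `se`, `intercept`, `n_points`.
#' @export
fit_linear_rate <- function(curve) {
  stopifnot(inherits(curve, "progress_curve"))
  t <- curve$time_min; y <- curve$signal_au
  if (length(t) < 3L) stop("need at least 3 points for a linear rate")
  fit <- stats::lm(y ~ t)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(rate = unname(sm[2, 1]), se = unname(sm[2, 2]),
       intercept = unname(sm[1, 1]), n_points = length(t))
}

#' Fit a whole progress-curve family and assemble the kobs profile
#'
#' Fits [fit_progress_curve()] to every curve of an experiment sharing one
#' design except for the inhibitor concentration, and collects
#' `(inhibitor_nM, kobs, se)` for all curves with a reportable kobs into a
#' `kobs_profile` (sorted by concentration). Curves that do not converge or
#' show no detectable curvature (typically the uninhibited control and the
#' lowest concentrations) are excluded from the profile and listed with
#' reasons; all per-curve fits are kept in the `fits` element.
#'
#' @param curves a list of [progress_curve()] objects (e.g. from
#'   [simulate_experiment()] or [read_progress_curves()]).
#' @param ... passed to [fit_progress_curve()].
#' @return an object of class `kobs_profile`: a list with `profile` (a
#'   data.frame with columns inhibitor_nM, kobs, se), `fits`, `excluded`
#'   (data.frame of curve_id, inhibitor_nM, reason).
#' @export
batch_fit <- function(curves, ...) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, TRUE, "progress_curve")))
  S <- vapply(curves, `[[`, 0, "substrate_uM")
  E <- vapply(curves, `[[`, 0, "enzyme_nM")
  if (length(unique(S)) != 1L || length(unique(E)) != 1L)
    stop("curves must share the same design except for [I]")
  fits <- lapply(curves, fit_progress_curve, ...)
  ok <- vapply(fits, function(f) f$converged && !f$linear &&
                 is.finite(f$kobs), TRUE)
  excluded <- data.frame(
    curve_id = vapply(fits[!ok], `[[`, "", "curve_id"),
    inhibitor_nM = vapply(fits[!ok], `[[`, 0, "inhibitor_nM"),
    reason = vapply(fits[!ok], function(f)
      if (!f$converged) "non-convergent" else "no detectable curvature",
      ""),
    stringsAsFactors = FALSE)
  profile <- data.frame(
    inhibitor_nM = vapply(fits[ok], `[[`, 0, "inhibitor_nM"),
    kobs = vapply(fits[ok], `[[`, 0, "kobs"),
    se = vapply(fits[ok], function(f) f$se[["kobs"]], 0))
  profile <- profile[order(profile$inhibitor_nM), , drop = FALSE]
  rownames(profile) <- NULL
  structure(list(profile = profile, fits = fits, excluded = excluded),
            class = "kobs_profile")
}

#' @export
print.kobs_profile <- function(x, ...) {
  cat(sprintf("kobs profile: %d concentrations (%d curves excluded)\n",
              nrow(x$profile), nrow(x$excluded)))
  print(x$profile, row.names = FALSE)
  invisible(x)
}
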