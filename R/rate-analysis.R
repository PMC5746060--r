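# corrected Akaike information criterion from an RSS, Gaussian errors
.aicc_rss <- function(rss, n, k) {
  # k model parameters + 1 for the error variance
  kk <- k + 1
  aic <- n * log(rss / n) + 2 * kk
  if (n - kk - 1 > 0) aic + 2 * kk * (kk + 1) / (n - kk - 1) else Inf
}

#' Linear analysis of the kobs-vs-inhibitor profile
#'
#' For simple one-step slow binding, kobs depends linearly on the inhibitor
#' concentration: `kobs = koff + kon * I`. Ordinary (optionally
#' 1/SE^2-weighted) linear regression of the profile therefore yields the
#' association rate constant `kon` (slope, nM^-1 min^-1), the dissociation
#' rate constant `koff` (intercept, min^-1) and the apparent inhibitory
#' constant `Kiapp = koff / kon` (nM). The standard error of `Kiapp` is
#' obtained by first-order (delta-method) propagation using the full
#' slope-intercept covariance.
#'
#' A fitted intercept more than 2 SE below zero has no physical reading
#' (`koff >= 0`); in that case a warning is emitted and `Kiapp` is withheld
#' (`NA`) rather than clamped.
#'
#' @param profile a `kobs_profile` from [batch_fit()], or a data.frame with
#'   columns `inhibitor_nM`, `kobs` and optionally `se`.
#' @param weighted if `TRUE`, weight points by `1/se^2`.
#' @return an object of class `slow_binding_fit` with `model =
#'   "one_step_linear"`, `kon`, `koff`, `Kiapp`, their SEs, `rss`, `aicc`,
#'   `n`.
#' @export
fit_kobs_linear <- function(profile, weighted = FALSE) {
  d <- .as_profile_df(profile)
  if (nrow(d) < 3L) stop("need kobs at >= 3 inhibitor concentrations")
  if (length(unique(d$inhibitor_nM)) < 2L)
    stop("singular design: all concentrations identical")
  w <- if (weighted) {
    if (is.null(d$se) || any(!is.finite(d$se)) || any(d$se <= 0))
      stop("weighted fit requires finite positive SEs")
    1 / d$se^2
  } else rep(1, nrow(d))
  fit <- stats::lm(kobs ~ inhibitor_nM, data = d, weights = w)
  cf <- stats::coef(fit)
  V <- suppressWarnings(stats::vcov(fit))
  koff <- unname(cf[1]); kon <- unname(cf[2])
  se_koff <- sqrt(V[1, 1]); se_kon <- sqrt(V[2, 2])
  out <- list(model = "one_step_linear", kon = kon, koff = koff,
              Kiapp = NA_real_, se = c(kon = se_kon, koff = se_koff,
                                       Kiapp = NA_real_),
              rss = sum(w * stats::residuals(fit)^2),
              aicc = .aicc_rss(sum(stats::residuals(fit)^2), nrow(d), 2L),
              n = nrow(d), weighted = weighted,
              data = d, flags = character(0))
  class(out) <- "slow_binding_fit"
  if (kon <= 0) {
    out$flags <- c(out$flags, "non-positive slope: Kiapp undefined")
    warning("kobs profile has non-positive slope; Kiapp withheld")
    return(out)
  }
  if (koff < -2 * se_koff) {
    out$flags <- c(out$flags,
                   "intercept negative beyond 2 SE: Kiapp withheld")
    warning("fitted koff is negative beyond 2 SE; Kiapp withheld")
    return(out)
  }
  out$Kiapp <- koff / kon
  # delta method: Var(koff/kon) with slope-intercept covariance
  g <- c(1 / kon, -koff / kon^2)          # d(Kiapp)/d(koff, kon)
  out$se[["Kiapp"]] <- sqrt(drop(t(g) %*% V[c(1, 2), c(1, 2)] %*% g))
  out
}

.as_profile_df <- function(profile) {
  d <- if (inherits(profile, "kobs_profile")) profile$profile else profile
  stopifnot(is.data.frame(d),
            all(c("inhibitor_nM", "kobs") %in% names(d)))
  if (any(d$inhibitor_nM < 0)) stop("inhibitor concentrations must be >= 0")
  d
}

#' @export
print.slow_binding_fit <- function(x, ...) {
  cat("Slow-binding fit:", x$model, "\n")
  if (x$model == "one_step_linear") {
    cat(sprintf("  kon   = %g +/- %g nM^-1 min^-1\n", x$kon, x$se[["kon"]]))
    cat(sprintf("  koff  = %g +/- %g min^-1\n", x$koff, x$se[["koff"]]))
    cat(sprintf("  Kiapp = %g +/- %g nM (koff/kon)\n",
                x$Kiapp, x$se[["Kiapp"]]))
  } else {
    cat(sprintf("  k6  = %g +/- %g min^-1\n", x$k6, x$se[["k6"]]))
    cat(sprintf("  k5  = %g +/- %g min^-1\n", x$k5, x$se[["k5"]]))
    cat(sprintf("  Ki1 = %g +/- %g nM\n", x$Ki1, x$se[["Ki1"]]))
  }
  cat(sprintf("  n = %d, AICc = %.2f\n", x$n, x$aicc))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Hyperbolic (two-step) analysis of the kobs profile
#'
#' Fits the saturating dependence `kobs = k6 + k5 * I / (Ki1 + I)`
#' diagnostic of two-step binding (E + I <-> EI <-> EI*), as the
#' alternative against which the linear one-step model is compared by
#' [compare_kobs_models()]. On intrinsically linear data `Ki1` runs to the
#' upper bound (the hyperbola degenerates to a line), which is reported as
#' a flag.
#'
#' @inheritParams fit_kobs_linear
#' @return a `slow_binding_fit` with `model = "two_step_hyperbolic"` and
#'   `k5`, `k6`, `Ki1` with SEs.
#' @export
fit_kobs_hyperbolic <- function(profile) {
  d <- .as_profile_df(profile)
  if (nrow(d) < 5L) stop("need kobs at >= 5 inhibitor concentrations")
  Imax <- max(d$inhibitor_nM)
  start <- list(k6 = max(min(d$kobs), 1e-6),
                k5 = max(max(d$kobs) - min(d$kobs), 1e-6),
                Ki1 = stats::median(d$inhibitor_nM))
  upper_Ki1 <- 1e4 * Imax
  do_fit <- function(ctrl) tryCatch(
    minpack.lm::nlsLM(kobs ~ k6 + k5 * inhibitor_nM / (Ki1 + inhibitor_nM),
                      data = d, start = start,
                      lower = c(k6 = 0, k5 = 0, Ki1 = 1e-6),
                      upper = c(k6 = Inf, k5 = Inf, Ki1 = upper_Ki1),
                      control = ctrl),
    error = function(e) e)
  fit <- do_fit(minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-14, ptol = 1e-14))
  if (inherits(fit, "error"))    # exact-fit degeneracy at tight tolerances
    fit <- do_fit(minpack.lm::nls.lm.control(maxiter = 500))
  out <- list(model = "two_step_hyperbolic", k5 = NA_real_, k6 = NA_real_,
              Ki1 = NA_real_,
              se = c(k5 = NA_real_, k6 = NA_real_, Ki1 = NA_real_),
              rss = NA_real_, aicc = Inf, n = nrow(d),
              data = d, converged = FALSE, flags = character(0))
  class(out) <- "slow_binding_fit"
  if (inherits(fit, "error")) {
    out$flags <- c(out$flags, paste("non-convergent:",
                                    conditionMessage(fit)))
    return(out)
  }
  cf <- stats::coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) stats::setNames(
                    rep(NA_real_, 3L), names(cf)))
  out$k6 <- unname(cf["k6"]); out$k5 <- unname(cf["k5"])
  out$Ki1 <- unname(cf["Ki1"])
  out$se <- c(k5 = unname(ses["k5"]), k6 = unname(ses["k6"]),
              Ki1 = unname(ses["Ki1"]))
  out$rss <- sum(stats::residuals(fit)^2)
  out$aicc <- .aicc_rss(out$rss, nrow(d), 3L)
  out$converged <- TRUE
  if (out$Ki1 >= 0.99 * upper_Ki1)
    out$flags <- c(out$flags,
                   "Ki1 at upper bound: profile indistinguishable from linear")
  out
}

#' Select between the one-step (linear) and two-step (hyperbolic) models
#'
#' Corrected-AIC comparison of the two fits of the same kobs profile. The
#' hyperbolic model, being the more complex one, is only preferred when its
#' AICc improves on the linear model's by at least `delta` (default 2);
#' ties and everything short of that go to the linear model. An F-test on
#' the residual sums of squares is reported as secondary evidence (the
#' models are not strictly nested, so it is advisory).
#'
#' @param linear a `slow_binding_fit` from [fit_kobs_linear()].
#' @param hyperbolic a `slow_binding_fit` from [fit_kobs_hyperbolic()].
#' @param delta AICc margin required to accept the more complex model.
#' @return a list with `selected` (`"one_step_linear"` or
#'   `"two_step_hyperbolic"`), `delta_aicc` (AICc linear - AICc
#'   hyperbolic), `aicc`, and `f_p_value`.
#' @export
compare_kobs_models <- function(linear, hyperbolic, delta = 2) {
  stopifnot(inherits(linear, "slow_binding_fit"),
            inherits(hyperbolic, "slow_binding_fit"),
            linear$model == "one_step_linear",
            hyperbolic$model == "two_step_hyperbolic")
  if (!isTRUE(all.equal(linear$data[c("inhibitor_nM", "kobs")],
                        hyperbolic$data[c("inhibitor_nM", "kobs")])))
    stop("the two fits were not computed on identical data")
  d_aicc <- linear$aicc - hyperbolic$aicc
  n <- linear$n
  f_p <- if (isTRUE(hyperbolic$converged) && hyperbolic$rss < linear$rss &&
             n - 3 > 0) {
    Fstat <- ((linear$rss - hyperbolic$rss) / 1) / (hyperbolic$rss / (n - 3))
    stats::pf(Fstat, 1, n - 3, lower.tail = FALSE)
  } else NA_real_
  selected <- if (isTRUE(hyperbolic$converged) && d_aicc >= delta)
    "two_step_hyperbolic" else "one_step_linear"
  list(selected = selected, delta_aicc = d_aicc,
       aicc = c(one_step_linear = linear$aicc,
                two_step_hyperbolic = hyperbolic$aicc),
       f_p_value = f_p)
}

#' Test whether the initial rate vi is independent of inhibitor concentration
#'
#' For one-step slow binding the inhibitor has not bound at t = 0, so the
#' initial rate of every progress curve equals the uninhibited rate. A
#' decreasing trend of vi with [I] instead indicates a fast (instantaneous)
#' binding component. This test regresses the fitted vi values on [I] and
#' t-tests the slope against zero.
#'
#' @param fits a `kobs_profile` (its per-curve fit ledger is used), or a
#'   list of `progress_fit` objects, or a data.frame with columns
#'   `inhibitor_nM` and `vi`.
#' @param alpha significance level.
#' @param tol practical-equivalence bound: a trend whose total predicted
#'   change in vi across the concentration range is below `tol` times the
#'   mean vi is declared independent regardless of its p value (fitter
#'   round-off on exact data is statistically "significant" but
#'   scientifically nil).
#' @return a list with `slope`, `se`, `p_value`, `verdict` (`"independent"`
#'   or `"dependent"`), `n`.
#' @export
test_vi_independence <- function(fits, alpha = 0.05, tol = 1e-4) {
  d <- if (inherits(fits, "kobs_profile")) {
    keep <- vapply(fits$fits, function(f) f$converged && is.finite(f$vi),
                   TRUE)
    data.frame(
      inhibitor_nM = vapply(fits$fits[keep], `[[`, 0, "inhibitor_nM"),
      vi = vapply(fits$fits[keep], `[[`, 0, "vi"))
  } else if (is.data.frame(fits)) {
    fits
  } else {
    data.frame(inhibitor_nM = vapply(fits, `[[`, 0, "inhibitor_nM"),
               vi = vapply(fits, `[[`, 0, "vi"))
  }
  if (nrow(d) < 3L) stop("need vi at >= 3 inhibitor concentrations")
  fit <- stats::lm(vi ~ inhibitor_nM, data = d)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(sm[2, 1]); se <- unname(sm[2, 2])
  # noise-free data can give an exactly zero residual variance
  p <- if (se == 0) (if (slope == 0) 1 else 0) else unname(sm[2, 4])
  rel_effect <- abs(slope) * diff(range(d$inhibitor_nM)) /
    max(mean(abs(d$vi)), .Machine$double.eps)
  list(slope = slope, se = se, p_value = p,
       verdict = if (p <= alpha && rel_effect >= tol) "dependent"
                 else "independent",
       n = nrow(d))
}
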