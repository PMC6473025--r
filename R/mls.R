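#' Maximal-lifespan (MLS) estimate
#'
#' MLS here is the mean lifespan of the longest-lived 10% of a cohort (not
#' the single maximum).  An estimate carries its value in months, an
#' uncertainty half-width `delta` (P = 0.05 where computable, `NA`
#' otherwise), the number of animals in the tail it averages over, and a
#' method tag.
#'
#' @param value MLS in months, positive.
#' @param delta Half-width of the 95% confidence interval in months
#'   (nonnegative), or `NA` when no standard uncertainty is defined.
#' @param n_tail Number of animals averaged (NA for model-based methods).
#' @param method One of `"direct"`, `"model_tail"`, `"combined"`.
#' @return An object of class `mls_estimate`.
#' @export
mls_estimate <- function(value, delta = NA_real_, n_tail = NA_integer_,
                         method = c("direct", "model_tail", "combined")) {
  method <- match.arg(method)
  stopifnot(is.numeric(value), length(value) == 1L, value > 0)
  if (!is.na(delta) && delta < 0) stop("delta must be nonnegative")
  structure(list(value = as.numeric(value), delta = as.numeric(delta),
                 n_tail = n_tail, method = method),
            class = "mls_estimate")
}

#' @export
print.mls_estimate <- function(x, ...) {
  d <- if (is.na(x$delta)) "" else sprintf(" ± %.2f", x$delta)
  cat(sprintf("MLS (%s): %.2f%s months", x$method, x$value, d))
  if (!is.na(x$n_tail)) cat(sprintf(" [top %d animals]", x$n_tail))
  cat("\n")
  invisible(x)
}

#' Direct MLS: mean lifespan of the top decile
#'
#' Averages the `k = max(1, floor(fraction * n_cohort))` largest death
#' ages.  With the default fraction 0.1 this is the mean lifespan of the
#' 10% most long-lived animals (k = 2 of 20, k = 5 of 51).  The attached
#' `delta` is the Student-t 95% half-width of the tail ages ([student_ci()]),
#' or `NA` when the tail holds a single animal.
#'
#' @param death_ages All death ages of the cohort after the mortality
#'   policy, in months (any order).
#' @param n_cohort Cohort size defining the decile; defaults to
#'   `length(death_ages)`.  A warning is issued below 10 animals.
#' @param fraction Tail fraction, default 0.1.
#' @return An [mls_estimate()] with method `"direct"`.
#' @export
mls_direct <- function(death_ages, n_cohort = length(death_ages),
                       fraction = 0.1) {
  if (length(death_ages) == 0L) stop("no death ages supplied")
  stopifnot(all(is.finite(death_ages)), n_cohort >= 1,
            fraction > 0, fraction <= 0.5)
  if (n_cohort < 10)
    warning("fewer than 10 animals; top-decile estimate is a single-digit tail")
  k <- max(1L, floor(fraction * n_cohort))
  if (k > length(death_ages))
    stop("tail size exceeds number of recorded death ages")
  top <- sort(death_ages, decreasing = TRUE)[seq_len(k)]
  delta <- if (k >= 2L) student_ci(top) else NA_real_
  mls_estimate(mean(top), delta, n_tail = k, method = "direct")
}

#' Model-based MLS: tail conditional mean of the fitted survival curve
#'
#' Evaluates the conditional mean age over \eqn{[t_{10}, \infty)} with the
#' model survival function \eqn{f(t)} itself as the integral weight,
#' \deqn{\mathrm{MLS} = \frac{\int_{t_{10}}^{\infty} t\, f(t)\, dt}
#'                           {\int_{t_{10}}^{\infty} f(t)\, dt},}
#' where \eqn{t_{10}} is the age at which the surviving fraction equals
#' `fraction` (10% by default).  Integrals use adaptive quadrature
#' ([stats::integrate()]) truncated where \eqn{f < 10^{-12}}; the result
#' always exceeds \eqn{t_{10}}.
#'
#' Note the weight is the survival function as the estimator defines it,
#' not the death density; the density-weighted version
#' \eqn{E[T \mid T > t_{10}]} is a different (larger) quantity.
#'
#' @param params A [gompertz_params()] object.
#' @param fraction Surviving fraction defining the tail onset, default 0.1.
#' @param rel_tol Relative quadrature tolerance, default 1e-8.
#' @return An [mls_estimate()] with method `"model_tail"` and attribute
#'   `"t_tail"` (the integration lower limit in months).
#' @export
mls_model_tail <- function(params, fraction = 0.1, rel_tol = 1e-8) {
  stopifnot(inherits(params, "gompertz_params"),
            fraction > 0, fraction < 1)
  t_lo <- quantile_time(params, fraction)
  t_hi <- quantile_time(params, 1e-12)  # truncate where f < 1e-12
  num <- stats::integrate(function(t) t * survival_fraction(params, t),
                          t_lo, t_hi, rel.tol = rel_tol)
  den <- stats::integrate(function(t) survival_fraction(params, t),
                          t_lo, t_hi, rel.tol = rel_tol)
  if (num$message != "OK" || den$message != "OK")
    stop(sprintf("quadrature failed (residual estimates %g, %g)",
                 num$abs.error, den$abs.error))
  out <- mls_estimate(num$value / den$value, NA_real_, NA_integer_,
                      method = "model_tail")
  attr(out, "t_tail") <- t_lo
  out
}

#' Uncertainty-weighted combination of two MLS estimates
#'
#' Combines two estimates with weights inverse to their uncertainties:
#' \deqn{\mathrm{MLS} = \frac{\Delta_2 v_1 + \Delta_1 v_2}{\Delta_1 + \Delta_2},}
#' so the estimate with the smaller half-width gets the larger weight and
#' the result is a convex combination of the two values.  The combined
#' half-width is the heuristic `min(delta1, delta2)` (flagged via the
#' `delta_method` element); no exact propagation formula is defined for
#' this combination.
#'
#' @param e1,e2 [mls_estimate()] objects with nonnegative `delta`s, at
#'   most one of them zero.
#' @param delta1,delta2 Override half-widths (months); default to the
#'   estimates' own `delta`s.
#' @return An [mls_estimate()] with method `"combined"` and an extra
#'   element `delta_method = "min_heuristic"`.
#' @export
combine_weighted <- function(e1, e2, delta1 = e1$delta, delta2 = e2$delta) {
  stopifnot(inherits(e1, "mls_estimate"), inherits(e2, "mls_estimate"))
  if (is.na(delta1) || is.na(delta2))
    stop("both estimates need an uncertainty half-width to combine")
  if (delta1 < 0 || delta2 < 0) stop("deltas must be nonnegative")
  if (delta1 == 0 && delta2 == 0) {
    if (e1$value != e2$value)
      stop("both deltas zero with unequal values: combination undefined")
    return(mls_estimate(e1$value, 0, NA_integer_, method = "combined"))
  }
  value <- (delta2 * e1$value + delta1 * e2$value) / (delta1 + delta2)
  out <- mls_estimate(value, min(delta1, delta2), NA_integer_,
                      method = "combined")
  out$delta_method <- "min_heuristic"
  out
}

#' Student-t confidence half-width
#'
#' Standard 95% (by default) confidence half-width
#' \eqn{t_{n-1,\,1-\alpha/2}\, s/\sqrt{n}} with `s` the sample standard
#' deviation.
#'
#' @param ages Numeric sample, n >= 2.
#' @param alpha Significance level, default 0.05.
#' @return Half-width in the units of `ages`.
#' @export
student_ci <- function(ages, alpha = 0.05) {
  n <- length(ages)
  if (n < 2L) stop("CI undefined for fewer than 2 observations")
  stats::qt(1 - alpha / 2, df = n - 1) * stats::sd(ages) / sqrt(n)
}

#' Percent extension of maximal lifespan
#'
#' \eqn{100 (\mathrm{MLS}^{exp} - \mathrm{MLS}^{C}) / \mathrm{MLS}^{C}}.
#'
#' @param mls_exp Treated-group MLS, months.
#' @param mls_ctrl Control MLS, months; must be positive.
#' @return Extension in percent.
#' @export
extension_percent <- function(mls_exp, mls_ctrl) {
  if (mls_ctrl <= 0) stop("control MLS must be positive")
  100 * (mls_exp - mls_ctrl) / mls_ctrl
}

#' Fold change in survival time past the intervention age
#'
#' \eqn{(\mathrm{MLS}^{exp} - t_0)/(\mathrm{MLS}^{C} - t_0)}: how many
#' times longer the treated animals' remaining maximal lifespan is,
#' counted from the intervention age `t0`.
#'
#' @inheritParams extension_percent
#' @param t0 Intervention age in months; both MLS values must exceed it.
#' @return Fold change (1 = no effect).
#' @export
survival_fold <- function(mls_exp, mls_ctrl, t0) {
  if (mls_ctrl <= t0) stop("fold undefined: control MLS does not exceed t0")
  if (mls_exp <= t0) stop("fold undefined: experimental MLS does not exceed t0")
  (mls_exp - t0) / (mls_ctrl - t0)
}
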