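#' Gompertz mortality-law parameters
#'
#' Container for the two parameters of the Gompertz law with exponentially
#' increasing hazard \eqn{h(t) = e^{\mu_0 + \mu_1 t}}.  Ages are in months
#' throughout: `mu0` is the log baseline hazard (per month) and `mu1` the
#' hazard slope (1/month).
#'
#' Two normalizations of the survival function are supported:
#' \describe{
#'   \item{`proper`}{\eqn{S(t) = \exp(-(e^{\mu_0+\mu_1 t} - e^{\mu_0})/\mu_1)},
#'     the textbook form with \eqn{S(0) = 1} exactly.  This is the default
#'     and the form used for sampling and fitting.}
#'   \item{`paper_literal`}{\eqn{S(t) = \exp(-e^{\mu_0+\mu_1 t}/\mu_1)}, the
#'     survival kernel as sometimes printed with the starting population as
#'     the 100\% scale.  It misses 1 at \eqn{t=0} by
#'     \eqn{e^{\mu_0}/\mu_1} in log-survival (about \eqn{1.6\times 10^{-5}}
#'     at typical fitted values), so the two forms agree to better than
#'     \eqn{10^{-4}} absolute.}
#' }
#'
#' @param mu0 Log baseline hazard (dimensionless log of a per-month rate).
#' @param mu1 Hazard slope, 1/month; must be strictly positive.
#' @param normalization `"proper"` (default) or `"paper_literal"`; see
#'   Details.
#' @return An object of class `gompertz_params`.
#' @examples
#' p <- gompertz_params(-11.4, 0.7)
#' survival_fraction(p, 15)
#' quantile_time(p, 0.1)
#' @export
gompertz_params <- function(mu0, mu1,
                            normalization = c("proper", "paper_literal")) {
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(mu0), length(mu0) == 1L, is.finite(mu0),
            is.numeric(mu1), length(mu1) == 1L, is.finite(mu1))
  if (mu1 <= 0) stop("mu1 must be strictly positive")
  structure(list(mu0 = as.numeric(mu0), mu1 = as.numeric(mu1),
                 normalization = normalization),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz parameters: mu0 = %g, mu1 = %g 1/month (%s)\n",
              x$mu0, x$mu1, x$normalization))
  invisible(x)
}

stopifnot_params <- function(params) {
  if (!inherits(params, "gompertz_params"))
    stop("`params` must be a gompertz_params object")
  params
}

#' Model survival fraction at age t
#'
#' Fraction of the starting population surviving to age `t` under the
#' Gompertz law.  Vectorized over `t`.
#'
#' @param params A [gompertz_params()] object.
#' @param t Age(s) in months, nonnegative.
#' @return Survival fraction(s) in (0, 1].
#' @export
survival_fraction <- function(params, t) {
  stopifnot_params(params)
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be nonnegative and finite")
  with(params, switch(normalization,
    proper        = exp(-(exp(mu0 + mu1 * t) - exp(mu0)) / mu1),
    paper_literal = exp(-exp(mu0 + mu1 * t) / mu1)
  ))
}

#' Gompertz hazard rate
#'
#' Instantaneous mortality rate \eqn{e^{\mu_0 + \mu_1 t}} (per month).
#'
#' @inheritParams survival_fraction
#' @export
hazard_rate <- function(params, t) {
  stopifnot_params(params)
  if (any(t < 0)) stop("t must be nonnegative")
  exp(params$mu0 + params$mu1 * t)
}

#' Age at which a given fraction of the population survives
#'
#' Closed-form inverse of [survival_fraction()]: returns the age `t` with
#' `survival_fraction(params, t) == q`.  Under the proper normalization
#' \eqn{t = (\log(e^{\mu_0} - \mu_1 \log q) - \mu_0)/\mu_1}.
#'
#' @inheritParams survival_fraction
#' @param q Surviving fraction(s), strictly inside (0, 1).
#' @return Age(s) in months.
#' @export
quantile_time <- function(params, q) {
  stopifnot_params(params)
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("q must lie strictly inside (0, 1)")
  with(params, switch(normalization,
    proper        = (log(exp(mu0) - mu1 * log(q)) - mu0) / mu1,
    paper_literal = (log(-mu1 * log(q)) - mu0) / mu1
  ))
}

#' Sample lifespans by exact inverse-CDF draws
#'
#' Draws `n` death ages from the Gompertz law by mapping uniform deviates
#' through [quantile_time()]; exact (no discretization) and reproducible
#' under `seed`.
#'
#' @inheritParams survival_fraction
#' @param n Number of lifespans, at least 1.
#' @param seed Optional integer seed; when supplied the global RNG state is
#'   restored on exit.
#' @return Numeric vector of `n` ages in months.
#' @export
sample_lifespans <- function(params, n, seed = NULL) {
  stopifnot_params(params)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  quantile_time(params, stats::runif(n))
}

#' Least-squares fit of the Gompertz law to an empirical survival curve
#'
#' Minimizes the sum of squared deviations between the model survival
#' fraction and the empirical step curve, evaluated at the step's lower
#' value immediately after each distinct death age (the "loss of animals"
#' at that age).  A multistart grid over \eqn{\mu_0 \in [-20,-5]},
#' \eqn{\mu_1 \in [0.1, 2]} feeds Nelder--Mead refinement; the best start
#' is polished once more.  Deterministic for a given curve.
#'
#' @param curve A [step_curve()] with at least 3 distinct death ages.
#' @param normalization Normalization of the fitted law; see
#'   [gompertz_params()].
#' @return A `gompertz_params` object with attribute `"residual"` (the
#'   minimized sum of squares).
#' @export
fit_least_squares <- function(curve, normalization = "proper") {
  stopifnot(inherits(curve, "step_curve"))
  pts <- curve$breakpoints
  pts <- pts[pts$age_months > 0, , drop = FALSE]  # drop the (0, 1) anchor
  if (nrow(pts) < 3L) stop("need at least 3 distinct death ages to fit")
  tt <- pts$age_months
  yy <- pts$fraction_surviving

  objective <- function(par) {
    if (par[2] <= 0) return(1e10)
    p <- structure(list(mu0 = par[1], mu1 = par[2],
                        normalization = normalization),
                   class = "gompertz_params")
    sum((survival_fraction(p, tt) - yy)^2)
  }

  starts <- expand.grid(mu0 = seq(-20, -5, length.out = 4),
                        mu1 = seq(0.1, 2, length.out = 5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[i, ]), objective,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish the winning start
  best <- stats::optim(best$par, objective, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 5000))
  if (!is.finite(best$value))
    stop(sprintf("least-squares fit failed to converge (best residual %g)",
                 best$value))
  out <- gompertz_params(best$par[1], best$par[2], normalization)
  attr(out, "residual") <- best$value
  out
}

#' Serialize / deserialize Gompertz parameters as JSON
#'
#' @param params A `gompertz_params` object.
#' @param path File path.
#' @return `read_params_json` returns a `gompertz_params` object.
#' @export
write_params_json <- function(params, path) {
  stopifnot_params(params)
  jsonlite::write_json(list(mu0 = params$mu0, mu1 = params$mu1,
                            normalization = params$normalization),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gompertz_params(x$mu0, x$mu1, x$normalization)
}
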