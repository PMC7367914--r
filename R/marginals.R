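#' Truncated parameter marginals
#'
#' A `marginal` describes the population distribution of one model parameter:
#' a distribution family (`normal`, `lognormal`, `weibull` or `fixed`), its
#' two shape parameters, and a truncation range `[lower, upper]` in parameter
#' units.  Sampling and quantile evaluation always go through the truncated
#' distribution, implemented by CDF renormalisation (inverse-CDF mapping), so
#' that stratified or quasi-random uniform designs stay uniform after the
#' transform.
#'
#' Parameterisation: for `normal`, `p1` is the mean and `p2` the **variance**;
#' for `lognormal`, `p1`/`p2` are the mean and **variance of the log values**;
#' for `weibull`, `p1` is the shape and `p2` the scale.  `fixed` marginals
#' carry a single constant `value`.
#'
#' @param name parameter label.
#' @param family one of `"normal"`, `"lognormal"`, `"weibull"`, `"fixed"`.
#' @param p1,p2 shape parameters (see Details); ignored for `fixed`.
#' @param lower,upper truncation bounds in parameter units.
#' @param value constant for the `fixed` family.
#' @param unit optional unit string (metadata only).
#' @return an object of class `marginal`.
#' @examples
#' m <- marginal("BW", "lognormal", 4.30, 3.8e-2, lower = 30, upper = 200)
#' qmarginal(m, 0.5)
#' @export
marginal <- function(name, family = c("normal", "lognormal", "weibull",
                                      "fixed", "uniform"),
                     p1 = NULL, p2 = NULL, lower = -Inf, upper = Inf,
                     value = NULL, unit = NA_character_) {
  family <- match.arg(family)
  spec <- structure(
    list(name = as.character(name), family = family,
         p1 = p1, p2 = p2,
         lower = as.numeric(lower), upper = as.numeric(upper),
         value = value, unit = unit),
    class = "marginal")
  validate_marginal(spec)
  spec
}

validate_marginal <- function(spec) {
  stopifnot(inherits(spec, "marginal"))
  if (!is.finite(spec$lower) && spec$family != "fixed" && spec$family != "normal")
    stop("non-normal families need a finite lower bound or none at all")
  if (!(spec$lower < spec$upper))
    stop("marginal '", spec$name, "': lower must be < upper")
  if (spec$family == "fixed") {
    if (is.null(spec$value) || !is.finite(spec$value))
      stop("fixed marginal '", spec$name, "' needs a finite value")
    if (spec$value < spec$lower || spec$value > spec$upper)
      stop("fixed marginal '", spec$name, "': value outside [lower, upper]")
    return(invisible(spec))
  }
  if (is.null(spec$p1) || is.null(spec$p2) ||
      !is.finite(spec$p1) || !is.finite(spec$p2))
    stop("marginal '", spec$name, "' needs finite p1 and p2")
  if (spec$family == "uniform") {
    if (spec$p1 >= spec$p2)
      stop("marginal '", spec$name, "': uniform needs p1 < p2")
    return(invisible(spec))
  }
  if (spec$p2 <= 0)
    stop("marginal '", spec$name, "': p2 (variance or scale) must be > 0")
  if (spec$family == "weibull" && spec$p1 <= 0)
    stop("marginal '", spec$name, "': weibull shape must be > 0")
  invisible(spec)
}

# untruncated CDF / quantile of the underlying family
.marg_p <- function(spec, x) {
  switch(spec$family,
    normal    = stats::pnorm(x, spec$p1, sqrt(spec$p2)),
    lognormal = stats::plnorm(x, spec$p1, sqrt(spec$p2)),
    weibull   = stats::pweibull(x, shape = spec$p1, scale = spec$p2),
    uniform   = stats::punif(x, spec$p1, spec$p2),
    stop("no CDF for family ", spec$family))
}

.marg_q <- function(spec, p) {
  switch(spec$family,
    normal    = stats::qnorm(p, spec$p1, sqrt(spec$p2)),
    lognormal = stats::qlnorm(p, spec$p1, sqrt(spec$p2)),
    weibull   = stats::qweibull(p, shape = spec$p1, scale = spec$p2),
    uniform   = stats::qunif(p, spec$p1, spec$p2),
    stop("no quantile for family ", spec$family))
}

# truncation mass F(upper) - F(lower); cached per call, cheap anyway
.marg_trunc_mass <- function(spec) {
  flo <- .marg_p(spec, spec$lower)
  fhi <- .marg_p(spec, spec$upper)
  if (fhi - flo < 1e-12)
    stop("marginal '", spec$name, "': degenerate support, ",
         "truncation mass below tolerance")
  c(flo = flo, fhi = fhi)
}

#' Truncated quantile function
#'
#' Maps `u` in `[0, 1]` to parameter values through the truncated
#' distribution: `F^{-1}(F(lower) + u (F(upper) - F(lower)))` for the
#' untruncated family CDF `F`.  `fixed` marginals return their constant for
#' any `u`.
#'
#' @param spec a [marginal()].
#' @param u vector of probabilities in `[0, 1]`.
#' @return parameter values, monotone non-decreasing in `u` and contained in
#'   `[lower, upper]`.
#' @export
qmarginal <- function(spec, u) {
  validate_marginal(spec)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("u must lie in [0, 1]")
  if (spec$family == "fixed")
    return(rep(spec$value, length(u)))
  m <- .marg_trunc_mass(spec)
  x <- .marg_q(spec, m[[1]] + u * (m[[2]] - m[[1]]))
  pmin(pmax(x, spec$lower), spec$upper)
}

#' Truncated CDF
#'
#' Inverse of [qmarginal()]: probability mass of the truncated distribution
#' below `x`.  For `fixed` marginals returns a step at the constant.
#'
#' @param spec a [marginal()].
#' @param x parameter values inside `[lower, upper]`.
#' @export
pmarginal <- function(spec, x) {
  validate_marginal(spec)
  if (any(x < spec$lower - 1e-12) || any(x > spec$upper + 1e-12))
    stop("x outside the truncation range [", spec$lower, ", ", spec$upper, "]")
  if (spec$family == "fixed")
    return(as.numeric(x >= spec$value))
  m <- .marg_trunc_mass(spec)
  u <- (.marg_p(spec, x) - m[[1]]) / (m[[2]] - m[[1]])
  pmin(pmax(u, 0), 1)
}

#' Sample a truncated marginal
#'
#' @param spec a [marginal()].
#' @param n number of draws.
#' @return `n` draws from the truncated distribution (inverse-CDF sampling).
#' @export
rmarginal <- function(spec, n) {
  qmarginal(spec, stats::runif(n))
}

#' @export
print.marginal <- function(x, ...) {
  if (x$family == "fixed") {
    cat(sprintf("<marginal> %s: fixed at %g", x$name, x$value))
  } else {
    cat(sprintf("<marginal> %s: %s(p1 = %g, p2 = %g) truncated to [%g, %g]",
                x$name, x$family, x$p1, x$p2, x$lower, x$upper))
  }
  if (!is.na(x$unit)) cat(" [", x$unit, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Select the best-fitting marginal family by AIC
#'
#' Fits normal, lognormal and Weibull distributions to the data by maximum
#' likelihood and returns the family with the lowest AIC (`2k - 2 logL`,
#' `k = 2` for all three families).  This mirrors the distribution-selection
#' step used to condense virtual-population samples into parametric
#' marginals.  Ties are broken in the order normal, lognormal, weibull.
#' Non-positive observations exclude the lognormal and Weibull candidates.
#'
#' @param data numeric vector of at least 30 finite observations.
#' @param name label for the returned marginal.
#' @param lower,upper truncation bounds attached to the returned spec
#'   (default: the data range widened by 1\%); the likelihoods themselves are
#'   untruncated.
#' @return a [marginal()] of the winning family, with an `aic` attribute
#'   giving the AIC of every candidate.
#' @export
fit_marginal <- function(data, name = "fitted", lower = NULL, upper = NULL) {
  data <- as.numeric(data)
  if (length(data) < 30) stop("need at least 30 observations")
  if (any(!is.finite(data))) stop("data must be finite")
  if (stats::var(data) < .Machine$double.eps)
    stop("degenerate data: zero variance")
  families <- c("norm", "lnorm", "weibull")
  if (any(data <= 0)) families <- "norm"
  fits <- list()
  for (fam in families) {
    fits[[fam]] <- tryCatch(
      fitdistrplus::fitdist(data, fam),
      error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no candidate distribution converged")
  aic <- vapply(fits, function(f) 2 * 2 - 2 * f$loglik, numeric(1))
  best <- names(fits)[which.min(aic)]  # which.min keeps first on ties
  est <- fits[[best]]$estimate
  rng <- range(data)
  span <- diff(rng)
  if (is.null(lower)) lower <- rng[1] - 0.01 * span
  if (is.null(upper)) upper <- rng[2] + 0.01 * span
  spec <- switch(best,
    norm    = marginal(name, "normal", est[["mean"]], est[["sd"]]^2,
                       lower, upper),
    lnorm   = marginal(name, "lognormal", est[["meanlog"]], est[["sdlog"]]^2,
                       lower, upper),
    weibull = marginal(name, "weibull", est[["shape"]], est[["scale"]],
                       lower, upper))
  attr(spec, "aic") <- stats::setNames(aic, names(fits))
  spec
}
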