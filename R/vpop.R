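#' Sample a correlated virtual population
#'
#' Gaussian-copula sampling: draws standard multivariate normal scores with
#' the requested latent correlation, maps each coordinate through the
#' standard-normal CDF to uniforms and then through the truncated marginal
#' quantile functions.  Parameters absent from the correlation matrix are
#' sampled independently; `fixed`-family marginals are broadcast constants.
#' Marginal distributions are exactly preserved for any admissible
#' correlation matrix (the copula only reshuffles ranks).
#'
#' @param marginals named list of [marginal()] objects (e.g.
#'   `drug_spec("quinidine")$marginals`).
#' @param corr optional [correlation_spec()]; labels must be a subset of the
#'   marginal names.  `NULL` samples everything independently.
#' @param n number of virtual subjects.
#' @param seed integer seed (stored with the table).
#' @return a `data.frame` of class `population`, one row per subject, one
#'   column per marginal, with attributes `seed` and `marginals`.
#' @examples
#' qd <- drug_spec("quinidine")
#' pop <- sample_population(qd$marginals, default_correlation(qd),
#'                          n = 100, seed = 1)
#' summary(pop$BW)
#' @export
sample_population <- function(marginals, corr = NULL, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  nms <- vapply(marginals, function(m) m$name, character(1))
  names(marginals) <- nms
  k <- length(marginals)
  u <- matrix(stats::runif(n * k), n, k, dimnames = list(NULL, nms))
  if (!is.null(corr)) {
    stopifnot(inherits(corr, "correlation_spec"))
    lab <- corr$labels
    if (!all(lab %in% nms))
      stop("correlation labels not found in marginals: ",
           paste(setdiff(lab, nms), collapse = ", "))
    z <- rmvnorm_chol(n, corr$matrix)
    u[, lab] <- stats::pnorm(z)
  }
  out <- as.data.frame(
    lapply(stats::setNames(nms, nms), function(nm) qmarginal(marginals[[nm]], u[, nm])))
  attr(out, "seed") <- seed
  attr(out, "marginals") <- marginals
  class(out) <- c("population", "data.frame")
  out
}

# correlated standard-normal scores via eigen factorisation (PSD-safe)
rmvnorm_chol <- function(n, sigma) {
  k <- ncol(sigma)
  e <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  fac <- e$vectors %*% diag(sqrt(lam), k)
  z <- matrix(stats::rnorm(n * k), n, k) %*% t(fac)
  colnames(z) <- colnames(sigma)
  z
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d subjects x %d parameters (seed %s)\n",
              nrow(x), ncol(x), format(attr(x, "seed"))))
  NextMethod()
}

#' Write / read a population table as CSV
#'
#' Plain CSV with a header row of parameter labels.
#'
#' @param pop a `population` (or plain data frame).
#' @param path file path.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("population", "data.frame")
  out
}

#' Fit marginals and an adjusted correlation matrix to a population
#'
#' The distribution-condensation workflow applied to a virtual-population
#' table: each varying column gets the best of normal / lognormal / Weibull
#' by AIC ([fit_marginal()]), and the empirical Pearson correlation matrix is
#' sparsified by significance and magnitude ([adjust_correlation()]).
#'
#' @param pop population table (rows = subjects).
#' @param alpha,r_min thresholds passed to [adjust_correlation()].
#' @return list with `marginals` (named list of fitted [marginal()]s) and
#'   `corr` (adjusted [correlation_spec()]).
#' @export
fit_population <- function(pop, alpha = 0.05, r_min = 0.1) {
  x <- as.data.frame(pop)
  keep <- vapply(x, function(col) stats::var(col) > .Machine$double.eps,
                 logical(1))
  fits <- lapply(stats::setNames(names(x)[keep], names(x)[keep]),
                 function(nm) fit_marginal(x[[nm]], name = nm))
  est <- estimate_correlation(x[, keep, drop = FALSE])
  list(marginals = fits,
       corr = adjust_correlation(est$corr, est$p_values,
                                 alpha = alpha, r_min = r_min))
}
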