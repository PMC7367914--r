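#' Labelled correlation matrices
#'
#' A `correlation_spec` is a labelled, symmetric, unit-diagonal Pearson
#' correlation matrix used as the dependence structure of the Gaussian copula
#' (the correlation of the latent normal scores).  Matrices are required to
#' be positive semi-definite up to a small tolerance; slightly indefinite
#' matrices (as routinely produced by entrywise adjustment) are repaired by
#' eigenvalue clipping, see [nearest_psd()].
#'
#' @param matrix square numeric matrix of correlations.
#' @param labels parameter names; defaults to the matrix dimnames.
#' @param repair if `TRUE` (default), project an indefinite matrix to the
#'   nearest positive semi-definite correlation matrix, recording the repair;
#'   the projection is rejected if it moves any entry by more than
#'   `max_repair`.
#' @param max_repair largest admissible entrywise change during repair.
#' @return an object of class `correlation_spec`.
#' @export
correlation_spec <- function(matrix, labels = NULL, repair = TRUE,
                             max_repair = 0.05) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("correlation matrix must be square")
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("x", seq_len(nrow(m)))
  if (length(labels) != nrow(m)) stop("labels do not match matrix dimension")
  dimnames(m) <- list(labels, labels)
  if (max(abs(m - t(m))) > 1e-8) stop("correlation matrix must be symmetric")
  m <- (m + t(m)) / 2
  if (max(abs(diag(m) - 1)) > 1e-8) stop("diagonal must be 1")
  if (any(abs(m) > 1 + 1e-8)) stop("entries must lie in [-1, 1]")
  repaired <- FALSE
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    if (!repair) stop("matrix is not positive semi-definite")
    m2 <- nearest_psd(m)
    if (max(abs(m2 - m)) > max_repair)
      stop("PSD repair would change an entry by more than ", max_repair)
    m <- m2
    repaired <- TRUE
  }
  structure(list(labels = labels, matrix = m, repaired = repaired),
            class = "correlation_spec")
}

#' Nearest positive semi-definite correlation matrix
#'
#' Eigenvalue clipping at zero followed by diagonal renormalisation back to
#' unit diagonal.
#'
#' @param m symmetric matrix with unit diagonal.
#' @return a positive semi-definite correlation matrix.
#' @export
nearest_psd <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  m2 <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(m2))
  d[d < 1e-12] <- 1
  m2 <- m2 / tcrossprod(d)
  diag(m2) <- 1
  dimnames(m2) <- dimnames(m)
  (m2 + t(m2)) / 2
}

#' @export
print.correlation_spec <- function(x, ...) {
  cat(sprintf("<correlation_spec> %d parameters%s\n", length(x$labels),
              if (isTRUE(x$repaired)) " (PSD-repaired)" else ""))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Estimate a correlation matrix from a population table
#'
#' Pairwise Pearson correlations with two-sided p-values for the null of
#' zero correlation, via the t-distribution transform
#' `t = r sqrt((n-2)/(1-r^2))`.  Constant columns get correlation 0 and
#' p-value 1 with a warning record.
#'
#' @param pop data frame or matrix, one row per subject, one column per
#'   varying parameter (e.g. from [sample_population()]).
#' @return a list with elements `corr` (a [correlation_spec()]) and
#'   `p_values` (matrix of the same shape).
#' @export
estimate_correlation <- function(pop) {
  x <- as.matrix(pop)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 subjects")
  const <- apply(x, 2, stats::var) < .Machine$double.eps
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  if (any(const)) {
    warning("constant columns: ", paste(colnames(x)[const], collapse = ", "),
            "; their correlations set to 0 with p = 1")
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  rr <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- rr * sqrt((n - 2) / (1 - rr^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  if (any(const)) { p[const, ] <- 1; p[, const] <- 1 }
  diag(p) <- 0
  dimnames(p) <- dimnames(r)
  list(corr = correlation_spec(r), p_values = p)
}

#' Sparsify an estimated correlation matrix
#'
#' Sets off-diagonal entries that are statistically non-significant
#' (`p > alpha`) or very weak (`|r| < r_min`) to zero, then re-projects the
#' result to the nearest positive semi-definite correlation matrix.  With the
#' default thresholds this is the adjustment used to turn a raw
#' population-estimated matrix into the dependence structure handed to the
#' copula sampler and the extended Sobol engine.
#'
#' @param corr a [correlation_spec()].
#' @param p_values matrix of p-values matching `corr$matrix`.
#' @param alpha significance threshold (default 0.05).
#' @param r_min minimum absolute correlation kept (default 0.1).
#' @return an adjusted [correlation_spec()].  Idempotent.
#' @export
adjust_correlation <- function(corr, p_values, alpha = 0.05, r_min = 0.1) {
  stopifnot(inherits(corr, "correlation_spec"))
  m <- corr$matrix
  p <- as.matrix(p_values)
  if (!all(dim(p) == dim(m))) stop("p_values shape does not match matrix")
  drop <- (p > alpha) | (abs(m) < r_min)
  diag(drop) <- FALSE
  # alternating projections: enforce the zero pattern and PSD-ness jointly so
  # the operation is idempotent (a single clip can re-fill zeroed entries)
  for (i in 1:200) {
    m[drop] <- 0
    m2 <- nearest_psd(m)
    if (max(abs(m2 - m)) < 1e-12) { m <- m2; break }
    m <- m2
  }
  m[drop] <- 0
  correlation_spec(m, labels = corr$labels, max_repair = Inf)
}
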