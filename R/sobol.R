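#' Saltelli-style Sobol design
#'
#' Two `N x k` base matrices `A` and `B` filled by inverse-CDF transform of
#' stratified uniform streams (randomised Latin hypercube), plus the `k`
#' hybrid matrices `AB_i` (A with column `i` taken from B), for a total of
#' `N (k + 2)` model evaluations.  Sampling goes through the truncated
#' marginal distributions, as variance-based indices are defined with
#' respect to the parameter distributions (unlike Morris, which uses ranges
#' only).
#'
#' @param marginals named list of non-fixed [marginal()] objects.
#' @param N base sample size.
#' @param seed integer seed.
#' @return object of class `sobol_design` with matrices `A`, `B` (values)
#'   and `UA`, `UB` (uniforms).
#' @export
sobol_design <- function(marginals, N, seed = NULL) {
  stopifnot(N >= 2)
  if (!is.null(seed)) set.seed(seed)
  nms <- vapply(marginals, function(m) m$name, character(1))
  if (all(vapply(marginals, function(m) m$family == "fixed", logical(1))))
    stop("design is degenerate: all marginals are fixed")
  k <- length(marginals)
  U <- lhs::randomLHS(N, 2 * k)
  UA <- U[, seq_len(k), drop = FALSE]
  UB <- U[, k + seq_len(k), drop = FALSE]
  colnames(UA) <- colnames(UB) <- nms
  tr <- function(Um) {
    X <- Um
    for (j in seq_len(k)) X[, j] <- qmarginal(marginals[[j]], Um[, j])
    X
  }
  structure(list(A = tr(UA), B = tr(UB), UA = UA, UB = UB,
                 N = N, k = k, names = nms, seed = seed),
            class = "sobol_design")
}

#' Estimate Sobol indices from design evaluations
#'
#' First-order indices use the Saltelli (2010) estimator
#' `S_i = mean(fB (fAB_i - fA)) / V`, total-effect indices the Jansen
#' estimator `S_Ti = mean((fA - fAB_i)^2) / (2 V)`, with `V` the variance of
#' the pooled `fA`, `fB` evaluations.  Raw values are reported without
#' clipping, so small negative estimates remain visible as Monte-Carlo
#' noise.  Rows with non-finite output in any matrix are dropped pairwise
#' and counted.
#'
#' @param fA,fB numeric vectors of model outputs on `A` and `B` (length
#'   `N`).
#' @param fAB `N x k` matrix of outputs on the hybrid matrices.
#' @return list with vectors `S`, `ST`, `interaction` (= `ST - S`), scalar
#'   `V`, and `n_dropped`.
#' @export
estimate_sobol <- function(fA, fB, fAB) {
  fAB <- as.matrix(fAB)
  ok <- is.finite(fA) & is.finite(fB) & apply(is.finite(fAB), 1, all)
  n_dropped <- sum(!ok)
  fA <- fA[ok]; fB <- fB[ok]; fAB <- fAB[ok, , drop = FALSE]
  if (length(fA) < 2) stop("too few finite evaluations")
  V <- stats::var(c(fA, fB))
  if (V < 1e-300) stop("degenerate model output: zero variance")
  S <- colMeans(fB * (fAB - fA)) / V
  ST <- colMeans((fA - fAB)^2) / (2 * V)
  list(S = S, ST = ST, interaction = ST - S, V = V, n_dropped = n_dropped)
}

#' Variance-based Sobol sensitivity analysis
#'
#' Runs the full Saltelli design: samples [sobol_design()], evaluates the
#' model on `A`, `B` and every `AB_i`, and estimates first-order (`S_i`),
#' total (`S_Ti`) and interaction (`S_Ti - S_i`) indices per output.
#' Repetitions with distinct seeds quantify the Monte-Carlo dispersion of
#' the indices.
#'
#' @param model function mapping a numeric matrix (rows = parameter
#'   vectors, named columns) to a vector or matrix of outputs.
#' @param marginals named list of [marginal()] objects (non-fixed).
#' @param N base sample size per repetition.
#' @param seed integer seed for the first repetition.
#' @param n_reps number of repetitions (>= 1).
#' @param seeds optional explicit vector of per-repetition seeds
#'   (overrides `seed`).
#' @return object of class `sobol_gsa`: arrays `S`, `ST`, `interaction`
#'   of dimension `k x n_endpoints x n_reps`, their across-repetition
#'   means (`S_mean`, ...) and standard deviations (`S_sd`, ...), and
#'   bookkeeping (`N`, `n_evals`, `n_dropped`).
#' @examples
#' m <- list(marginal("x1", "normal", 0, 1, -8, 8),
#'           marginal("x2", "normal", 0, 1, -8, 8))
#' names(m) <- c("x1", "x2")
#' f <- function(X) X[, 1] + 2 * X[, 2]
#' sobol_gsa(f, m, N = 1000, seed = 1)
#' @export
sobol_gsa <- function(model, marginals, N = 8000, seed = 1, n_reps = 1,
                      seeds = NULL) {
  stopifnot(n_reps >= 1)
  if (is.null(seeds)) seeds <- seed + seq_len(n_reps) - 1
  stopifnot(length(seeds) == n_reps)
  nms <- vapply(marginals, function(m) m$name, character(1))
  names(marginals) <- nms
  k <- length(marginals)
  res <- vector("list", n_reps)
  failed <- 0L
  for (rep in seq_len(n_reps)) {
    res[[rep]] <- tryCatch({
      des <- sobol_design(marginals, N, seeds[rep])
      YA <- as.matrix(model(des$A))
      YB <- as.matrix(model(des$B))
      m <- ncol(YA)
      epn <- colnames(YA)
      if (is.null(epn)) epn <- paste0("y", seq_len(m))
      S <- ST <- matrix(NA_real_, k, m, dimnames = list(nms, epn))
      dropped <- 0L
      YABs <- vector("list", k)
      for (i in seq_len(k)) {
        ABi <- des$A
        ABi[, i] <- des$B[, i]
        YABs[[i]] <- as.matrix(model(ABi))
      }
      for (j in seq_len(m)) {
        fAB <- vapply(YABs, function(y) y[, j], numeric(N))
        est <- estimate_sobol(YA[, j], YB[, j], fAB)
        S[, j] <- est$S
        ST[, j] <- est$ST
        dropped <- dropped + est$n_dropped
      }
      list(S = S, ST = ST, dropped = dropped)
    }, error = function(e) e)
  }
  errs <- vapply(res, inherits, logical(1), "error")
  if (all(errs)) stop("all repetitions failed: ",
                      conditionMessage(res[[which(errs)[1]]]))
  if (any(errs) && sum(!errs) < 2 && n_reps > 1)
    stop("fewer than 2 repetitions survived")
  res <- res[!errs]
  arr <- function(field) {
    a <- simplify2array(lapply(res, `[[`, field))
    if (length(dim(a)) == 2) a <- array(a, c(dim(a), 1),
                                        dimnames = c(dimnames(a), list(NULL)))
    a
  }
  Sa <- arr("S"); STa <- arr("ST")
  msd <- function(a, f) apply(a, c(1, 2), f)
  structure(list(
    S = Sa, ST = STa, interaction = STa - Sa,
    S_mean = msd(Sa, mean), ST_mean = msd(STa, mean),
    interaction_mean = msd(STa - Sa, mean),
    S_sd = if (length(res) > 1) msd(Sa, stats::sd) else msd(Sa, function(v) NA_real_),
    ST_sd = if (length(res) > 1) msd(STa, stats::sd) else msd(STa, function(v) NA_real_),
    N = N, k = k, n_reps = length(res), n_failed = sum(errs),
    n_evals = length(res) * N * (k + 2),
    n_dropped = sum(vapply(res, `[[`, integer(1), "dropped")),
    seeds = seeds),
    class = "sobol_gsa")
}

#' Repeated GSA with dispersion
#'
#' Convenience wrapper enforcing the repeated-analysis contract: at least
#' two repetitions with (by default) distinct seeds, returning per-index
#' across-repetition means and standard deviations.
#'
#' @param method `"sobol"` or `"ext_sobol"`.
#' @param ... passed to [sobol_gsa()] or [ext_sobol_gsa()].
#' @param n_reps number of repetitions, >= 2.
#' @export
repeat_gsa <- function(method = c("sobol", "ext_sobol"), ..., n_reps = 10) {
  method <- match.arg(method)
  if (n_reps < 2) stop("repeated analysis needs n_reps >= 2")
  switch(method,
         sobol = sobol_gsa(..., n_reps = n_reps),
         ext_sobol = ext_sobol_gsa(..., n_reps = n_reps))
}

#' @export
print.sobol_gsa <- function(x, ...) {
  cat(sprintf("<sobol_gsa> N = %d, k = %d, %d repetition(s), %d evaluations\n",
              x$N, x$k, x$n_reps, x$n_evals))
  for (ep in colnames(x$S_mean)) {
    ord <- order(x$ST_mean[, ep], decreasing = TRUE)
    df <- data.frame(S = x$S_mean[ord, ep], ST = x$ST_mean[ord, ep],
                     interaction = x$interaction_mean[ord, ep])
    cat("endpoint", ep, "- top parameters by total effect:\n")
    print(utils::head(round(df, 4), 8))
  }
  invisible(x)
}

#' Tidy Sobol results
#'
#' @param x a `sobol_gsa` (or `ext_sobol_gsa`).
#' @return data frame with endpoint, parameter, S, ST, interaction,
#'   rep_sd columns, rank (by total effect) and influence class.
#' @export
as.data.frame.sobol_gsa <- function(x, ...) {
  out <- do.call(rbind, lapply(colnames(x$S_mean), function(ep) {
    d <- data.frame(endpoint = ep, parameter = rownames(x$S_mean),
                    S = x$S_mean[, ep], ST = x$ST_mean[, ep],
                    interaction = x$interaction_mean[, ep],
                    S_rep_sd = x$S_sd[, ep], ST_rep_sd = x$ST_sd[, ep])
    d$rank <- rank(-d$ST, ties.method = "first")
    d$class <- classify_influence(pmax(d$S, d$ST))
    d
  }))
  rownames(out) <- NULL
  out
}
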