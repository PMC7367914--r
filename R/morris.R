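#' Morris elementary-effects screening design
#'
#' Builds `r` randomised one-at-a-time trajectories on the `l`-level grid
#' `{0, 1/(l-1), ..., 1}` of the unit cube, with jump
#' `delta = l / (2 (l - 1))`.  Each trajectory starts from a random
#' admissible base point and perturbs every coordinate exactly once, in a
#' random order and with a random jump sign, so consecutive points differ in
#' exactly one coordinate by `+/- delta`.
#'
#' @param k number of parameters.
#' @param l number of grid levels (even values make `delta` grid-aligned).
#' @param r number of trajectories.
#' @param seed integer seed.
#' @return object of class `morris_design`: unit-cube evaluation matrix
#'   `points` (`r (k+1)` rows), `delta`, per-trajectory flip order and
#'   signs.
#' @export
morris_design <- function(k, l = 10, r, seed = NULL) {
  stopifnot(k >= 1, l >= 2, r >= 1)
  if (!is.null(seed)) set.seed(seed)
  delta <- l / (2 * (l - 1))
  levels <- (seq_len(l) - 1) / (l - 1)
  ok_up <- levels[levels + delta <= 1 + 1e-12]
  ok_dn <- levels[levels - delta >= -1e-12]
  if (!length(ok_up) || !length(ok_dn))
    stop("delta = ", delta, " incompatible with an l = ", l, " grid")
  pts <- matrix(NA_real_, r * (k + 1), k)
  order_mat <- matrix(NA_integer_, r, k)
  sign_mat <- matrix(NA_real_, r, k)
  for (tr in seq_len(r)) {
    d <- sample(c(-1, 1), k, replace = TRUE)
    base <- vapply(d, function(di)
      if (di > 0) sample(ok_up, 1) else sample(ok_dn, 1), numeric(1))
    ord <- sample.int(k)
    x <- base
    row0 <- (tr - 1) * (k + 1)
    pts[row0 + 1, ] <- x
    for (j in seq_len(k)) {
      i <- ord[j]
      x[i] <- x[i] + d[i] * delta
      pts[row0 + 1 + j, ] <- x
    }
    order_mat[tr, ] <- ord
    sign_mat[tr, ] <- d
  }
  structure(list(points = pts, k = k, l = l, r = r, delta = delta,
                 order = order_mat, sign = sign_mat, seed = seed),
            class = "morris_design")
}

#' Elementary effects and Morris summary statistics
#'
#' For each trajectory and parameter the elementary effect is
#' `EE_i = (f(x + Delta e_i) - f(x)) / Delta` in unit-cube scale (so effects
#' are comparable across parameters with different units); `mu` is the
#' signed mean, `mu_star` the mean absolute value and `sigma` the standard
#' deviation of the `r` effects.  The global ranking index is
#' `GI = sqrt(mu_star^2 + sigma^2)`.  Trajectories containing non-finite
#' outputs are dropped and counted.
#'
#' @param design a [morris_design()].
#' @param Y numeric vector or matrix of model outputs, one row per design
#'   point (columns = endpoints).
#' @param param_names optional parameter labels.
#' @return object of class `morris_gsa`: arrays `mu`, `mu_star`, `sigma`,
#'   `gi` (`k x n_endpoints`), plus `n_dropped`.
#' @export
morris_indices <- function(design, Y, param_names = NULL) {
  stopifnot(inherits(design, "morris_design"))
  Y <- as.matrix(Y)
  k <- design$k; r <- design$r
  if (nrow(Y) != r * (k + 1))
    stop("outputs not aligned with the design (expected ",
         r * (k + 1), " rows)")
  m <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(m))
  if (is.null(param_names)) param_names <- paste0("x", seq_len(k))
  ee <- array(NA_real_, c(r, k, m))
  for (tr in seq_len(r)) {
    rows <- (tr - 1) * (k + 1) + seq_len(k + 1)
    ytr <- Y[rows, , drop = FALSE]
    if (any(!is.finite(ytr))) next
    for (j in seq_len(k)) {
      i <- design$order[tr, j]
      step <- design$sign[tr, i] * design$delta
      ee[tr, i, ] <- (ytr[j + 1, ] - ytr[j, ]) / step
    }
  }
  kept <- !is.na(ee[, 1, 1])
  if (!any(kept)) stop("all trajectories produced non-finite outputs")
  stat <- function(f) {
    out <- matrix(NA_real_, k, m, dimnames = list(param_names, colnames(Y)))
    for (j in seq_len(m)) out[, j] <- apply(ee[kept, , j, drop = FALSE], 2, f)
    out
  }
  mu <- stat(mean)
  mu_star <- stat(function(v) mean(abs(v)))
  sigma <- stat(stats::sd)
  if (sum(kept) < 2) sigma[] <- 0
  structure(list(mu = mu, mu_star = mu_star, sigma = sigma,
                 gi = global_index(mu_star, sigma),
                 n_dropped = sum(!kept), r_used = sum(kept),
                 design = design[c("k", "l", "r", "delta", "seed")]),
            class = "morris_gsa")
}

#' Morris global ranking index
#'
#' `GI = sqrt(mu_star^2 + sigma^2)`, combining overall influence and
#' interaction/non-linearity spread into a single ranking metric.
#'
#' @param mu_star mean absolute elementary effect (>= 0).
#' @param sigma standard deviation of elementary effects (>= 0).
#' @export
global_index <- function(mu_star, sigma) {
  if (any(mu_star < 0) || any(sigma < 0)) stop("mu_star, sigma must be >= 0")
  sqrt(mu_star^2 + sigma^2)
}

#' Morris screening of a model over parameter ranges
#'
#' Samples the unit-cube trajectory design, maps it linearly onto the given
#' `[min, max]` ranges (Morris screening uses ranges only, not the marginal
#' distributions), evaluates the model and summarises the elementary
#' effects.
#'
#' @param model function taking a numeric matrix (one row per evaluation,
#'   columns named by parameter) and returning a vector or matrix of
#'   outputs.
#' @param ranges 2-column matrix (`min`, `max`) with one named row per
#'   parameter.
#' @param l,r,seed design settings, see [morris_design()].
#' @return a `morris_gsa` object, see [morris_indices()].
#' @examples
#' f <- function(X) 2 * X[, 1]
#' rg <- cbind(min = c(0, 0), max = c(1, 1))
#' rownames(rg) <- c("a", "b")
#' morris_gsa(f, rg, l = 4, r = 20, seed = 1)
#' @export
morris_gsa <- function(model, ranges, l = 10, r = 200, seed = NULL) {
  ranges <- as.matrix(ranges)
  k <- nrow(ranges)
  des <- morris_design(k, l, r, seed)
  X <- sweep(des$points, 2, ranges[, 2] - ranges[, 1], `*`)
  X <- sweep(X, 2, ranges[, 1], `+`)
  colnames(X) <- rownames(ranges)
  morris_indices(des, model(X), param_names = rownames(ranges))
}

#' @export
print.morris_gsa <- function(x, ...) {
  cat(sprintf("<morris_gsa> k = %d, l = %d, r = %d (%d dropped), delta = %.4g\n",
              x$design$k, x$design$l, x$design$r, x$n_dropped, x$design$delta))
  for (ep in colnames(x$gi)) {
    cat("endpoint", ep, "- top parameters by GI:\n")
    ord <- order(x$gi[, ep], decreasing = TRUE)
    df <- data.frame(mu = x$mu[ord, ep], mu_star = x$mu_star[ord, ep],
                     sigma = x$sigma[ord, ep], gi = x$gi[ord, ep])
    print(utils::head(round(df, 4), 8))
  }
  invisible(x)
}

#' @export
plot.morris_gsa <- function(x, endpoint = colnames(x$gi)[1], ...) {
  graphics::plot(x$mu_star[, endpoint], x$sigma[, endpoint],
                 xlab = expression(mu * "*"), ylab = expression(sigma),
                 main = paste("Morris screening:", endpoint), ...)
  graphics::text(x$mu_star[, endpoint], x$sigma[, endpoint],
                 rownames(x$mu_star), pos = 3, cex = 0.7)
  invisible(x)
}

#' Tidy Morris results
#'
#' @param x a `morris_gsa`.
#' @return data frame with columns endpoint, parameter, mu, mu_star, sigma,
#'   gi, rank (by GI within endpoint).
#' @export
as.data.frame.morris_gsa <- function(x, ...) {
  out <- do.call(rbind, lapply(colnames(x$gi), function(ep) {
    d <- data.frame(endpoint = ep, parameter = rownames(x$gi),
                    mu = x$mu[, ep], mu_star = x$mu_star[, ep],
                    sigma = x$sigma[, ep], gi = x$gi[, ep])
    d$rank <- rank(-d$gi, ties.method = "first")
    d
  }))
  rownames(out) <- NULL
  out
}
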