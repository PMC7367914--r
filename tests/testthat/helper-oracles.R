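# Independent oracles shared across test files.

# truncated-CDF bisection: inverts F_trunc built directly from stats::p*
# (independent of the package's quantile path)
bisect_quantile <- function(pfun, lower, upper, u, tol = 1e-13) {
  flo <- pfun(lower); fhi <- pfun(upper)
  target <- flo + u * (fhi - flo)
  lo <- lower; hi <- upper
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (pfun(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# analytic mean/variance of a truncated standard-normal-family distribution
truncnorm_moments <- function(mean, sd, a, b) {
  al <- (a - mean) / sd; be <- (b - mean) / sd
  Z <- pnorm(be) - pnorm(al)
  m <- mean + sd * (dnorm(al) - dnorm(be)) / Z
  v <- sd^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z -
                 ((dnorm(al) - dnorm(be)) / Z)^2)
  list(mean = m, var = v)
}

# system matrix / input vector of the direct-clearance model, written out
# from the balance equations independently of the simulation code
pbpk_matrix_oracle <- function(pv, cl_uint, dose) {
  QH <- pv[["Q_HA"]] + pv[["Q_PV"]]
  V_sys <- (pv[["V_ss"]] * pv[["BW"]] - pv[["Kp_liver"]] * pv[["V_liver"]] +
              pv[["V_sac"]] * pv[["BW"]]) / pv[["BP"]]
  A <- matrix(0, 3, 3)
  A[1, 1] <- -(QH + pv[["CL_R"]] / pv[["BP"]]) / V_sys
  A[1, 3] <- QH * pv[["BP"]] / pv[["Kp_liver"]] / V_sys
  A[2, 1] <- pv[["Q_PV"]] / pv[["V_pv"]]
  A[2, 2] <- -pv[["Q_PV"]] / pv[["V_pv"]]
  A[3, 1] <- pv[["Q_HA"]] / pv[["V_liver"]]
  A[3, 2] <- pv[["Q_PV"]] / pv[["V_liver"]]
  A[3, 3] <- -(QH * pv[["BP"]] / pv[["Kp_liver"]] +
                 cl_uint * pv[["f_u"]] / pv[["Kp_liver"]]) / pv[["V_liver"]]
  b <- c(0, pv[["f_a"]] * pv[["k_a"]] * pv[["F_g"]] * dose / pv[["V_pv"]], 0)
  list(A = A, b = b, V_sys = V_sys)
}

# a minimal synthetic drug spec built in code (for unit tests that need a
# clearance model smaller than the bundled fixtures)
make_mm_drug <- function(abundance = "A", vm = 5.23, km = 2.16, mw = 325.8) {
  structure(list(
    name = "synthetic-mm", dose = 1, molecular_weight = mw,
    sac_enabled = FALSE, clearance_mode = "michaelis_menten",
    marginals = list(), pathways = list(list(
      enzyme = "ENZ", mode = "michaelis_menten", abundance = abundance,
      sub = list(list(vm = vm, km = km)))),
    varying = character(0), flows_normalized = FALSE),
    class = "drug_spec")
}
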