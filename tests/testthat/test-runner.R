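test_that("influence classes follow the 1% / 10% rules strictly", {
  expect_equal(classify_influence(c(0.005, 0.03, 0.5)),
               c("negligible", "influential", "key"))
  expect_equal(classify_influence(0.01), "negligible")   # strict inequality
  expect_equal(classify_influence(0.1), "influential")
  expect_error(classify_influence(NA_real_))
})

test_that("a parameter is classed on the larger of S and ST", {
  fake <- structure(list(
    S_mean = matrix(c(0.005, 0.3), 2, 1,
                    dimnames = list(c("a", "b"), "AUC_24h")),
    ST_mean = matrix(c(0.2, 0.002), 2, 1,
                     dimnames = list(c("a", "b"), "AUC_24h")),
    interaction_mean = matrix(0, 2, 1,
                              dimnames = list(c("a", "b"), "AUC_24h")),
    S_sd = matrix(NA_real_, 2, 1,
                  dimnames = list(c("a", "b"), "AUC_24h")),
    ST_sd = matrix(NA_real_, 2, 1,
                   dimnames = list(c("a", "b"), "AUC_24h"))),
    class = "sobol_gsa")
  df <- as.data.frame(fake)
  expect_equal(df$class[df$parameter == "a"], "key")  # via ST = 0.2
  expect_equal(df$class[df$parameter == "b"], "key")  # via S = 0.3
})

test_that("identical configurations reproduce bit-identical tables", {
  r1 <- run_gsa("quinidine", "sobol", endpoints = "AUC_24h", N = 200,
                seed = 11)
  r2 <- run_gsa("quinidine", "sobol", endpoints = "AUC_24h", N = 200,
                seed = 11)
  expect_identical(r1$tables, r2$tables)
  r3 <- run_gsa("quinidine", "sobol", endpoints = "AUC_24h", N = 200,
                seed = 12)
  expect_false(identical(r1$tables, r3$tables))
})

test_that("scenarios rewire marginals and correlations as intended", {
  fx <- default_fixture("alprazolam")
  nf <- apply_scenario(fx$drug, fx$corr, "normalized_flows")
  expect_true(all(c("Q_HA_hat", "Q_PV_hat") %in% nf$drug$varying))
  expect_false(any(c("Q_HA", "Q_PV") %in% nf$drug$varying))
  expect_equal(nf$drug$marginals$Q_PV_hat$p1, -0.11)
  expect_equal(nf$drug$marginals$Q_HA_hat$p1, -1.24)
  expect_equal(unname(nf$corr$matrix["BW", "Q_PV_hat"]), 0)
  expect_equal(unname(nf$corr$matrix["BW", "Q_HA_hat"]), 0)
  # other correlations survive
  expect_equal(unname(nf$corr$matrix["Kp_liver", "f_u"]), 0.9)
  # normalised flows are multiplied back by BW inside the model
  pv <- central_values(nf$drug)
  sim <- simulate_pbpk(nf$drug, pv)
  pv2 <- central_values(fx$drug)
  pv2[c("Q_HA", "Q_PV")] <- c(pv[["Q_HA_hat"]], pv[["Q_PV_hat"]]) * pv[["BW"]]
  sim2 <- simulate_pbpk(fx$drug, pv2)
  expect_equal(pk_endpoints(sim), pk_endpoints(sim2), tolerance = 1e-10)

  ic <- apply_scenario(fx$drug, fx$corr, "independent_cyps")
  expect_equal(unname(ic$corr$matrix["CL_int_CYP3A4", "CL_int_CYP3A5"]), 0)
  expect_equal(unname(ic$corr$matrix["Kp_liver", "f_u"]), 0.9)
  expect_equal(unname(ic$corr$matrix["BW", "Q_HA"]), 0.5)
})

test_that("high infeasible-subject rates abort distribution-based runs", {
  qd <- drug_spec("quinidine")
  qd$marginals$V_ss <- marginal("V_ss", "uniform", 1e-6, 0.2,
                                lower = 1e-6, upper = 0.2, unit = "L/kg")
  expect_error(run_gsa(qd, "sobol", endpoints = "AUC_24h", N = 100,
                       seed = 1), "infeasible")
})

test_that("the validation suite passes against all closed forms", {
  v <- validate_gsa(N = 2000, seed = 1, tol = 0.05)
  expect_s3_class(v, "gsa_validation")
  expect_true(attr(v, "ok"))
  expect_true(all(v$pass))
  expect_setequal(unique(v$check),
                  c("ishigami", "g-function", "linear-gaussian",
                    "morris-linear"))
})

test_that("Morris and Sobol agree on top parameters over population ranges", {
  # screening over quantile-trimmed (population-scaled) ranges reproduces
  # the variance-based top sets; raw bounds are loose simulator limits
  mq <- run_gsa("quinidine", "morris", r = 150, seed = 31,
                range_quantiles = c(0.001, 0.999))
  sq <- run_gsa("quinidine", "sobol", N = 1500, seed = 31)
  for (ep in c("T_max", "AUC_24h", "AUC_48h")) {
    mtop <- utils::head(mq$tables[[ep]]$parameter, 3)
    stop_ <- utils::head(sq$tables[[ep]]$parameter, 3)
    expect_gte(length(intersect(mtop, stop_)), 2)
  }
  # the two engines share the overall most influential parameter
  expect_equal(mq$tables$AUC_24h$parameter[1], sq$tables$AUC_24h$parameter[1])
})

test_that("extended Sobol reduces to Sobol for an identity fixture", {
  qd <- drug_spec("quinidine")
  id <- correlation_spec(diag(length(qd$varying)), qd$varying)
  eg <- run_gsa(qd, "ext_sobol", endpoints = "AUC_24h", N = 1000,
                seed = 41, corr = id, n_reps = 2)
  sg <- run_gsa(qd, "sobol", endpoints = "AUC_24h", N = 1000, seed = 41,
                n_reps = 2)
  for (p in c("CL_int_CYP3A4", "f_a", "BW")) {
    se <- sqrt(eg$result$ST_sd[p, 1]^2 + sg$result$ST_sd[p, 1]^2 +
                 eg$result$S_sd[p, 1]^2 + sg$result$S_sd[p, 1]^2)
    expect_lt(abs(eg$result$ST_mean[p, 1] - sg$result$ST_mean[p, 1]),
              3 * se + 0.03)
    expect_lt(abs(eg$result$S_mean[p, 1] - sg$result$S_mean[p, 1]),
              3 * se + 0.03)
  }
})

test_that("run manifests record the evaluation bookkeeping", {
  r <- run_gsa("alprazolam", "sobol", endpoints = "C_max", N = 100,
               seed = 51)
  expect_equal(r$manifest$drug, "alprazolam")
  expect_equal(r$manifest$n_evaluations, 100 * (15 + 2))
  expect_equal(r$manifest$settings$N, 100)
  expect_s3_class(r, "gsa_run")
  out <- utils::capture.output(print(r))
  expect_true(any(grepl("alprazolam", out)))
})

test_that("elimination fractions follow first-order kinetics", {
  expect_equal(fraction_cleared(24, 24), 0.5)
  expect_equal(fraction_cleared(0, 5), 0)
  # doubling the window squares the remaining fraction
  expect_equal(1 - fraction_cleared(48, 11.2),
               (1 - fraction_cleared(24, 11.2))^2)
  expect_error(fraction_cleared(24, 0))
})
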