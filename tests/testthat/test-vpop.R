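ln2 <- function(nm) marginal(nm, "lognormal", 0, 0.04, 1e-6, 10)
stdnorm <- function(nm) marginal(nm, "normal", 0, 1, -10, 10)

test_that("identity correlation yields independent columns", {
  m <- list(a = ln2("a"), b = ln2("b"))
  corr <- correlation_spec(diag(2), c("a", "b"))
  pop <- sample_population(m, corr, n = 5000, seed = 3)
  expect_lt(abs(cor(pop$a, pop$b)), 0.05)
})

test_that("the copula reproduces a strong target correlation", {
  m <- list(x = stdnorm("x"), y = stdnorm("y"))
  corr <- correlation_spec(matrix(c(1, 0.9, 0.9, 1), 2), c("x", "y"))
  pop <- sample_population(m, corr, n = 5000, seed = 4)
  r <- cor(pop$x, pop$y)
  expect_gte(r, 0.87)
  expect_lte(r, 0.93)
})

test_that("single-subject populations stay inside the truncation bounds", {
  qd <- drug_spec("quinidine")
  pop <- sample_population(qd$marginals, default_correlation(qd),
                           n = 1, seed = 5)
  expect_equal(nrow(pop), 1)
  for (m in qd$marginals)
    expect_true(pop[[m$name]] >= m$lower && pop[[m$name]] <= m$upper,
                info = m$name)
})

test_that("copula round trip recovers the latent matrix entrywise", {
  nms <- c("a", "b", "c", "d")
  target <- diag(4)
  target[1, 2] <- target[2, 1] <- 0.9
  target[3, 4] <- target[4, 3] <- 0.4
  target[1, 3] <- target[3, 1] <- -0.3
  corr <- correlation_spec(target, nms)
  m <- setNames(lapply(nms, stdnorm), nms)
  pop <- sample_population(m, corr, n = 5000, seed = 6)
  est <- estimate_correlation(pop)$corr$matrix
  expect_lt(max(abs(est - corr$matrix)), 0.04)
})

test_that("imposing correlation leaves the marginals unchanged", {
  qd <- drug_spec("quinidine")
  pop <- sample_population(qd$marginals, default_correlation(qd),
                           n = 2000, seed = 7)
  for (nm in c("BW", "f_u", "CL_int_CYP3A4", "f_a")) {
    spec <- qd$marginals[[nm]]
    ks <- suppressWarnings(ks.test(pop[[nm]], function(q) pmarginal(spec, q)))
    expect_gt(ks$p.value, 0.01, label = paste("K-S p for", nm))
  }
  # fixed parameters broadcast as constants
  expect_true(all(pop$V_sac == qd$marginals$V_sac$value))
})

test_that("pairwise correlation estimates behave at the extremes", {
  set.seed(8)
  x <- rnorm(500)
  pop <- data.frame(x = x, dup = x, neg = -x, u = runif(500))
  est <- estimate_correlation(pop)
  expect_equal(est$corr$matrix["x", "dup"], 1)
  expect_lt(est$p_values["x", "dup"], 1e-10)
  expect_equal(est$corr$matrix["x", "neg"], -1)
  expect_lt(abs(est$corr$matrix["x", "u"]), 0.1)
  expect_gt(est$p_values["x", "u"], 0.01)

  expect_warning(est2 <- estimate_correlation(cbind(pop, k = rep(1, 500))),
                 "constant")
  expect_equal(unname(est2$corr$matrix["k", "x"]), 0)
  expect_equal(unname(est2$p_values["k", "x"]), 1)
})

test_that("correlation adjustment zeroes weak and non-significant entries", {
  nms <- c("a", "b", "c")
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.08   # strong p, weak r -> dropped
  m[1, 3] <- m[3, 1] <- 0.5    # weak p -> dropped
  m[2, 3] <- m[3, 2] <- 0.6    # passes both -> kept
  p <- matrix(0, 3, 3)
  p[1, 2] <- p[2, 1] <- 0.001
  p[1, 3] <- p[3, 1] <- 0.20
  p[2, 3] <- p[3, 2] <- 0.001
  adj <- adjust_correlation(correlation_spec(m, nms), p)
  expect_equal(unname(adj$matrix[1, 2]), 0)
  expect_equal(unname(adj$matrix[1, 3]), 0)
  expect_equal(unname(adj$matrix[2, 3]), 0.6)
  # idempotence
  adj2 <- adjust_correlation(adj, p)
  expect_equal(adj2$matrix, adj$matrix, tolerance = 1e-10)
})

test_that("PSD repair clips eigenvalues and rejects large changes", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.95
  m[1, 3] <- m[3, 1] <- 0.95
  m[2, 3] <- m[3, 2] <- -0.5   # jointly infeasible
  expect_error(correlation_spec(m), "repair")
  fixed <- nearest_psd(m)
  ev <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(diag(fixed), rep(1, 3))
})

test_that("bundled fixtures carry the printed doses and parameter counts", {
  fq <- default_fixture("quinidine")
  expect_equal(fq$drug$dose, 200)
  expect_length(fq$drug$varying, 16)
  expect_equal(unname(fq$corr$matrix["Kp_liver", "f_u"]), 0.9)
  expect_equal(unname(fq$corr$matrix["BW", "Q_HA"]), 0.5)
  expect_equal(unname(fq$corr$matrix["CL_int_CYP3A4", "CL_int_CYP2C9"]), 0.4)

  fa <- default_fixture("alprazolam")
  expect_equal(fa$drug$dose, 0.5)
  expect_length(fa$drug$varying, 15)

  fm <- default_fixture("midazolam")
  expect_equal(fm$drug$dose, 5)
  expect_true(fm$drug$sac_enabled)
  expect_equal(fm$drug$marginals$K_out$value, 0.25)
  expect_equal(fm$drug$marginals$K_in$value, 0.2)
  expect_equal(fm$drug$marginals$V_sac$value, 0.23)
  expect_equal(unname(fm$corr$matrix["A_CYP3A4", "A_UGT1A4"]), 0.4)

  expect_error(drug_spec("nosuchdrug"), "unknown drug")
})

test_that("population fitting recovers families and sparsifies correlation", {
  qd <- drug_spec("quinidine")
  pop <- sample_population(qd$marginals, default_correlation(qd),
                           n = 800, seed = 9)
  fit <- fit_population(pop[, qd$varying])
  expect_named(fit, c("marginals", "corr"))
  # strongly skewed clearances should not come back normal
  expect_true(fit$marginals$CL_int_CYP3A4$family %in% c("lognormal", "weibull"))
  # the imposed strong link survives adjustment, absent links are zeroed
  expect_gt(fit$corr$matrix["Kp_liver", "f_u"], 0.5)
  expect_equal(unname(fit$corr$matrix["k_a", "CL_R"]), 0, tolerance = 1e-8)
  # round trip through CSV
  tf <- tempfile(fileext = ".csv")
  write_population(pop, tf)
  pop2 <- read_population(tf)
  expect_equal(as.data.frame(pop2), as.data.frame(pop), tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(tf)
})
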