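test_that("cochran_q matches analytic values and a summation oracle", {
  expect_equal(cochran_q(c(0.5, 0.5, 0.5), c(1, 2, 3))$q, 0)
  expect_equal(cochran_q(c(0.5, 0.5, 0.5), c(1, 2, 3))$p.value, 1)

  two <- cochran_q(c(0, 1), c(1, 1))
  expect_equal(two$pooled, 0.5)
  expect_equal(two$q, 0.5)
  expect_equal(two$df, 1L)

  set.seed(21)
  th <- rnorm(5); se <- runif(5, 0.5, 2)
  got <- cochran_q(th, se)
  w <- 1 / se^2
  tb <- sum(w * th) / sum(w)
  expect_equal(got$q, sum(w * (th - tb)^2), tolerance = 1e-12)
  expect_equal(got$p.value, pchisq(got$q, 4, lower.tail = FALSE))

  expect_error(cochran_q(c(0, 1), c(0, 1)), "zero SE")
  expect_error(cochran_q(1, 1), "At least 2")
})

test_that("joint OR grid reproduces exp(beta +/- 1.96 SE) and the reference", {
  sim <- sim_analysis_data(quick_config(n = 6000, seed = 41))
  fit <- fit_cell_model(sim$data, "any")
  grid <- joint_or_table(fit)
  expect_equal(grid$or[grid$quartile == 1 & grid$exposed == 0], 1)
  nz <- grid$log_or != 0
  z <- qnorm(0.975)
  expect_equal(grid$conf_low[nz], exp(grid$log_or[nz] - z * grid$se[nz]))
  expect_equal(grid$conf_high[nz], exp(grid$log_or[nz] + z * grid$se[nz]))
  expect_true(all(grid$conf_low[nz] <= grid$or[nz] &
                    grid$or[nz] <= grid$conf_high[nz]))
  V <- attr(grid, "vcov")
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
})

test_that("stratified ORs equal cell ratios exactly (saturated identity)", {
  sim <- sim_analysis_data(quick_config(n = 6000, seed = 42))
  fit <- fit_cell_model(sim$data, "any")
  grid <- joint_or_table(fit)
  strat <- stratified_or(grid)
  for (k in 1:4) {
    num <- grid$log_or[grid$quartile == k & grid$exposed == 1]
    den <- grid$log_or[grid$quartile == k & grid$exposed == 0]
    got <- strat$or[strat$contrast == "exposure_within_quartile" &
                      strat$quartile == k]
    expect_equal(log(got), num - den, tolerance = 1e-12)
  }
  for (q in 0:1) for (k in 2:4) {
    num <- grid$log_or[grid$quartile == k & grid$exposed == q]
    den <- grid$log_or[grid$quartile == 1 & grid$exposed == q]
    got <- strat$or[strat$contrast == "quartile_within_stratum" &
                      strat$quartile == k & strat$stratum == q]
    expect_equal(log(got), num - den, tolerance = 1e-12)
  }
  # identical numerator and denominator -> exactly 1
  same <- as_joint_or_table(
    tibble::tibble(quartile = rep(1:4, each = 2), exposed = rep(0:1, 4),
                   or = c(1, 1, 2, 2, 3, 3, 4, 4)))
  s <- stratified_or(same)
  expect_equal(s$or[s$contrast == "exposure_within_quartile"], rep(1, 4))
})

test_that("cell model recovers simulated truths and flags degenerate cells", {
  cfg <- quick_config(n = 20000, seed = 43)
  sim <- sim_analysis_data(cfg)
  fit <- fit_cell_model(sim$data, "any")
  grid <- joint_or_table(fit)
  truth <- sim$pop$truth$cell_logor
  for (i in seq_len(nrow(grid))[-1]) {
    tr <- truth[grid$quartile[i], grid$exposed[i] + 1]
    expect_lt(abs(grid$log_or[i] - tr), 2 * grid$se[i] + 0.02)
  }

  d_bad <- sim$data[sim$data$prs_q != 4 | sim$data$mht_any != 1, ]
  expect_error(fit_cell_model(d_bad, "any"), "Q4_exposed")
})

test_that("irrelevant constant covariates leave cell log-ORs unchanged", {
  cfg <- quick_config(n = 8000, seed = 44, n_studies = 1,
                      age_sd = 1e-9, bmi_sd = 1e-9, pc_sd = 1e-9,
                      beta_age = 0, beta_bmi = 0)
  sim <- sim_analysis_data(cfg)
  d <- sim$data
  d$age <- 60; d$bmi <- 27; d$pc1 <- d$pc2 <- d$pc3 <- 0; d$study <- "s1"
  f_with <- suppressMessages(fit_cell_model(d, "any"))
  f_without <- fit_cell_model(d, "any", covariates = character(0))
  expect_equal(coef(f_with$fit), coef(f_without$fit), tolerance = 1e-6)
})

test_that("trend test behaves under null and log-linear alternatives", {
  # null calibration: permuted outcomes give roughly uniform p-values
  cfg <- quick_config(n = 1200, seed = 45)
  sim <- sim_analysis_data(cfg)
  d <- sim$data
  set.seed(450)
  pvals <- replicate(120, {
    d$case_status <- sample(d$case_status)
    trend_test(d, "any", stratum = 0)$p.value
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.001)
  expect_between(mean(pvals < 0.05), 0.0, 0.12)

  # power: log-linear quartile effect detected in nearly all replicates
  hits <- vapply(1:15, function(i) {
    cfgp <- quick_config(n = 5000, seed = 500 + i,
                         quartile_logor = 0.35 * (1:3))
    simp <- sim_analysis_data(cfgp)
    trend_test(simp$data, "any", stratum = 0)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # missing quartile in the stratum is an error
  d2 <- sim$data[!(sim$data$prs_q == 4 & sim$data$mht_any == 1), ]
  expect_error(trend_test(d2, "any", stratum = 1), "quartiles")
})

test_that("joint fit and product-term reparameterization coincide", {
  sim <- sim_analysis_data(quick_config(n = 6000, seed = 46))
  fit <- fit_cell_model(sim$data, "any")
  models <- fit_interaction_models(sim$data, "any")
  expect_equal(as.numeric(logLik(fit$fit)), as.numeric(logLik(models$full)),
               tolerance = 1e-8)
  # fitted cell ORs agree between the two parameterizations
  grid <- joint_or_table(fit)
  b <- coef(models$full)
  or_q4_exp <- exp(b[["quartileQ4"]] + b[["exposure"]] +
                     b[["quartileQ4:exposure"]])
  expect_equal(grid$or[grid$quartile == 4 & grid$exposed == 1], or_q4_exp,
               tolerance = 1e-6)
})
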