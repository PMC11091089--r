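flat_rate <- function(rate) {
  tibble::tibble(age_start = 50, age_end = 80, rate_per_100k = rate)
}

test_that("attributable proportion matches trivial cases and a loop oracle", {
  expect_equal(attributable_proportion(rep("a", 5), c(a = 1, b = 2)), 0)
  expect_equal(attributable_proportion(rep("b", 4), c(a = 1, b = 2)), 0.5)
  set.seed(71)
  rr <- c(p1 = 1, p2 = 1.7, p3 = 2.9, p4 = 0.6)
  cases <- sample(names(rr), 200, replace = TRUE)
  oracle <- local({
    s <- 0
    for (cp in cases) s <- s + 1 / rr[[cp]]
    1 - s / length(cases)
  })
  expect_equal(attributable_proportion(cases, rr), oracle, tolerance = 1e-12)
  expect_error(attributable_proportion(character(0), rr), "At least one")
  expect_error(attributable_proportion("p1", c(p1 = -1)), "positive")
})

test_that("baseline hazard combines incidence and AP bands", {
  ap0 <- tibble::tibble(age_start = 50, age_end = 80, ap = 0)
  l0 <- baseline_hazard(flat_rate(100), ap0)
  expect_equal(unique(l0$lambda0), 0.001)
  ap5 <- tibble::tibble(age_start = 50, age_end = 80, ap = 0.5)
  expect_equal(unique(baseline_hazard(flat_rate(100), ap5)$lambda0), 0.0005)
  expect_error(baseline_hazard(flat_rate(100),
                               tibble::tibble(age_start = 50, age_end = 80,
                                              ap = 1.2)),
               "< 1")
  expect_error(baseline_hazard(flat_rate(100)[, ],
                               tibble::tibble(age_start = 60, age_end = 80,
                                              ap = 0)),
               "cover")
})

test_that("cumulative risk matches closed forms and monotonicity", {
  l0 <- tibble::tibble(age = 50:79, lambda0 = 0.001)
  m0 <- flat_rate(0)
  expect_equal(cumulative_risk(1, l0, m0), 100 * (1 - exp(-0.03)),
               tolerance = 1e-12)
  # zero incidence -> exactly 0
  lz <- tibble::tibble(age = 50:79, lambda0 = 0)
  expect_identical(cumulative_risk(1, lz, flat_rate(500)), 0)
  # age-increasing incidence beats constant with the same age-50 rate
  rising <- tibble::tibble(age = 50:79,
                           lambda0 = 0.001 * (1 + 0.03 * (50:79 - 50)))
  expect_gt(cumulative_risk(1, rising, m0), cumulative_risk(1, l0, m0))
  # longer horizon and less competing mortality increase risk
  expect_gt(cumulative_risk(1, l0, m0, 50, 80),
            cumulative_risk(1, l0, m0, 50, 70))
  expect_gt(cumulative_risk(1, l0, flat_rate(100)),
            cumulative_risk(1, l0, flat_rate(5000)))
  r <- cumulative_risk(3, l0, flat_rate(2000))
  expect_between(r, 0, 100)
})

test_that("cumulative risk agrees with a discrete-time microsimulation", {
  rt <- simulate_rate_tables()
  ap <- tibble::tibble(age_start = c(50, 61, 71), age_end = c(61, 71, 80),
                       ap = c(0.2, 0.3, 0.35))
  l0 <- baseline_hazard(rt$incidence, ap)
  rr <- tibble::tibble(age = 50:79,
                       rr = ifelse(50:79 <= 60, 2.5,
                                   ifelse(50:79 <= 70, 2.0, 1.6)))
  got <- cumulative_risk(rr, l0, rt$mortality)

  set.seed(72)
  N <- 200000
  alive <- rep(TRUE, N); event <- rep(FALSE, N)
  m <- prsgxe:::expand_rate_table(rt$mortality, 50:79)
  for (i in seq_along(50:79)) {
    h_d <- rr$rr[i] * l0$lambda0[i]
    h <- h_d + m[i]
    at_risk <- which(alive)
    ev <- at_risk[runif(length(at_risk)) < 1 - exp(-h)]
    is_crc <- runif(length(ev)) < h_d / h
    event[ev[is_crc]] <- TRUE
    alive[ev] <- FALSE
  }
  p_mc <- mean(event)
  se_mc <- sqrt(p_mc * (1 - p_mc) / N)
  expect_lt(abs(got / 100 - p_mc), 2 * se_mc)
})

test_that("baseline hazard back-calculation is self-consistent (sum to composite)", {
  # exact world: profile prevalences p_j and RRs give composite I = l0 * sum(p RR);
  # cases distributed proportional to p_j RR_j reproduce l0 exactly
  p <- c(a = 0.5, b = 0.25, c = 0.25)
  rr <- c(a = 1, b = 2, c = 4)
  l0_true <- 4e-4
  composite <- l0_true * sum(p * rr)
  # p * rr is proportional to 1:1:2, so an exact integer case mix exists
  cases <- rep(names(p), c(100, 100, 200))
  ap <- attributable_proportion(cases, rr)
  l0_back <- composite * (1 - ap)
  expect_lt(abs(l0_back - l0_true), 1e-10)
  # and the reconstructed composite matches the input
  expect_lt(abs(l0_back * sum(p * rr) - composite), 1e-10)
})

test_that("risk differences match worked values and flag degenerate SE", {
  expect_equal(risk_difference(6.1, 3.7)$difference, 2.4)
  expect_equal(risk_difference(2.2, 1.6)$difference, 0.6)
  expect_error(risk_difference(2, 1, 1:5, 1:4), "equal length")
  expect_warning(rd <- risk_difference(2, 1, rep(1, 5), rep(0.5, 5)),
                 "Degenerate")
  expect_true(is.na(rd$p.value))
  set.seed(73)
  b0 <- rnorm(100, 5, 0.4); b1 <- rnorm(100, 3, 0.3)
  rd2 <- risk_difference(5, 3, b0, b1)
  expect_equal(rd2$se, sd(b0 - b1))
  expect_equal(rd2$p.value, 2 * pnorm(-abs(2 / sd(b0 - b1))))
})

test_that("stratified bootstrap is deterministic and handles degeneracy", {
  cfg <- quick_config(n = 4000, seed = 74)
  sim <- sim_analysis_data(cfg)
  rt <- simulate_rate_tables()
  art1 <- absolute_risk_table(sim$data, rt$incidence, rt$mortality,
                              exposure = "any", B = 12, seed = 5)
  art2 <- absolute_risk_table(sim$data, rt$incidence, rt$mortality,
                              exposure = "any", B = 12, seed = 5)
  expect_identical(art1$risk, art2$risk)
  expect_identical(attr(art1, "replicates"), attr(art2, "replicates"))
  expect_true(all(art1$risk >= 0 & art1$risk <= 100))
  expect_true(all(art1$conf_low <= art1$risk & art1$risk <= art1$conf_high))

  # forced-identical resamples (single case and control per stratum sampled
  # with replacement from themselves) give a zero-width CI
  d1 <- tibble::tibble(case_status = c(1, 0), x = c(1, 2))
  br <- bootstrap_risks(d1, function(d) c(r = sum(d$x)), B = 2, seed = 1)
  expect_equal(unname(br$replicates[1, ]), unname(br$replicates[2, ]))
  expect_error(bootstrap_risks(d1, identity, B = 1), "At least 2")
  # failing replicates beyond the tolerated fraction abort
  expect_error(
    bootstrap_risks(d1, function(d) stop("boom"), B = 10),
    "bootstrap replicates failed")
})

test_that("bootstrap CIs cover the truth at reduced scale", {
  # truth: risk of each profile under the configured world, computed from
  # the true cell ORs and the same rate tables via the projection formula
  rt <- simulate_rate_tables()
  covered <- 0L
  n_outer <- 12
  for (i in seq_len(n_outer)) {
    cfg <- quick_config(n = 3000, seed = 800 + i, n_studies = 1)
    sim <- sim_analysis_data(cfg)
    truth_rr <- sim$pop$truth$cell_or["Q4", "unexposed"]
    # true AP in each band from the population case mix
    ph <- sim$pop$phenotypes
    cells <- paste0("Q", ph$prs_q_true, "_",
                    ifelse(ph$mht_any == 1, "exposed", "unexposed"))
    rr_true <- setNames(as.vector(t(sim$pop$truth$cell_or)),
                        paste0("Q", rep(1:4, each = 2), "_",
                               c("unexposed", "exposed")))
    ap_true <- attributable_proportion(cells[ph$case_status == 1], rr_true)
    ap_tbl <- tibble::tibble(age_start = 50, age_end = 80, ap = ap_true)
    l0 <- baseline_hazard(rt$incidence, ap_tbl)
    risk_true <- cumulative_risk(truth_rr, l0, rt$mortality)
    art <- suppressMessages(absolute_risk_table(
      sim$data, rt$incidence, rt$mortality, exposure = "any",
      B = 25, seed = i))
    row <- art[art$profile == "Q4_unexposed", ]
    if (row$conf_low <= risk_true && risk_true <= row$conf_high)
      covered <- covered + 1L
  }
  # nominal 95%: allow generous binomial slack at this scale
  expect_gte(covered, round(0.7 * n_outer))
})
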