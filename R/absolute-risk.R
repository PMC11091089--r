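#' Attributable proportion from the case distribution of risk profiles
#'
#' Case-distribution (Bruzzi-type) estimator: with relative risk `RR(p)` for
#' profile `p` and the profiles of the cases in an age group,
#' \deqn{AP = 1 - \frac{1}{n_{cases}} \sum_{cases} \frac{1}{RR(profile)}.}
#' Multiplying composite incidence by `1 - AP` converts it to the baseline
#' (reference-profile) hazard.
#'
#' @param case_profiles Character vector of profile labels, one per case.
#' @param rr Named positive numeric vector of relative risks per profile.
#' @return The attributable proportion (scalar, `< 1`).
#' @export
#' @examples
#' attributable_proportion(rep("hi", 4), c(hi = 2))  # 0.5
attributable_proportion <- function(case_profiles, rr) {
  if (!length(case_profiles)) abort("At least one case is required.")
  if (any(rr <= 0)) abort("Relative risks must be positive.")
  if (!all(case_profiles %in% names(rr)))
    abort("Every case profile must have a relative risk.")
  1 - mean(1 / rr[case_profiles])
}

# Expand a banded rate table (closed-open bands, rate per 100,000
# person-years) to per-year hazards over `ages` (each age a = interval
# [a, a+1)).
expand_rate_table <- function(tbl, ages, what = "rate") {
  need <- c("age_start", "age_end", "rate_per_100k")
  if (!all(need %in% names(tbl)))
    abort(paste0("Rate table must have columns: ", paste(need, collapse = ", ")))
  tbl <- dplyr::arrange(tbl, .data$age_start)
  if (any(tbl$rate_per_100k < 0)) abort("Negative rates are not allowed.")
  if (nrow(tbl) > 1 && any(tbl$age_start[-1] != tbl$age_end[-nrow(tbl)]))
    abort("Rate-table bands must be contiguous and non-overlapping.")
  band <- findInterval(ages, tbl$age_start)
  if (any(band == 0) || any(ages >= max(tbl$age_end)))
    abort(paste0("Rate table does not cover ages ", min(ages), "-",
                 max(ages) + 1, " (", what, ")."))
  tbl$rate_per_100k[band] / 1e5
}

# Expand per-age-group values (bands given as age_start/age_end) to ages.
expand_group_values <- function(tbl, ages, col) {
  band <- findInterval(ages, tbl$age_start)
  if (any(band == 0) || any(ages >= max(tbl$age_end)))
    abort("Age-group table does not cover the projection ages.")
  tbl[[col]][band]
}

#' Baseline age-specific hazard from composite incidence and attributable
#' proportions
#'
#' \eqn{\lambda_0(a) = I(a)\,(1 - AP_{g(a)})}, with `I(a)` the composite
#' incidence converted from per-100,000 person-years to per person-year and
#' `g(a)` the age group containing year-of-age `a` (piecewise-constant
#' within bands).
#'
#' @param incidence Incidence tibble (`age_start`, `age_end`,
#'   `rate_per_100k`).
#' @param ap Tibble with `age_start`, `age_end`, `ap` (attributable
#'   proportion per age group, each `< 1`).
#' @param ages Integer years of age to expand to (default 50-79).
#' @return Tibble with columns `age` and `lambda0` (per person-year).
#' @export
baseline_hazard <- function(incidence, ap, ages = 50:79) {
  if (any(ap$ap >= 1)) abort("Attributable proportions must be < 1.")
  inc <- expand_rate_table(incidence, ages, "incidence")
  apv <- expand_group_values(ap, ages, "ap")
  tibble::tibble(age = ages, lambda0 = inc * (1 - apv))
}

#' Cumulative disease risk over an age interval with competing mortality
#'
#' Discrete annual recursion with piecewise-constant cause-specific hazards:
#' with disease hazard \eqn{h_d(a) = RR(a)\,\lambda_0(a)}, competing
#' mortality \eqn{m(a)}, total hazard \eqn{h = h_d + m}, and survival
#' \eqn{S(a+1) = S(a) e^{-h(a)}} from \eqn{S(start) = 1}, the cumulative
#' risk is
#' \deqn{\sum_{a} S(a)\,[1 - e^{-h(a)}]\,\frac{h_d(a)}{h(a)},}
#' returned in percent. In the constant-hazard, no-competing-risk limit this
#' reduces to \eqn{100\,[1 - e^{-\lambda_0 (end - start)}]}.
#'
#' @param rr Relative risk of the profile: a scalar, or a tibble with
#'   columns `age` and `rr` for age-varying relative risks.
#' @param lambda0 Baseline hazard tibble from [baseline_hazard()] (`age`,
#'   `lambda0`, per person-year).
#' @param mortality Competing (non-disease) mortality rate table
#'   (`age_start`, `age_end`, `rate_per_100k`).
#' @param age_start,age_end Projection interval (default 50 to 80).
#' @return Cumulative risk in percent (scalar in `[0, 100]`).
#' @export
#' @examples
#' l0 <- tibble::tibble(age = 50:79, lambda0 = 0.001)
#' m0 <- tibble::tibble(age_start = 50, age_end = 80, rate_per_100k = 0)
#' cumulative_risk(1, l0, m0)  # 100 * (1 - exp(-0.03)) = 2.955
cumulative_risk <- function(rr, lambda0, mortality,
                            age_start = 50, age_end = 80) {
  ages <- seq(age_start, age_end - 1)
  l0 <- lambda0$lambda0[match(ages, lambda0$age)]
  if (anyNA(l0)) abort("`lambda0` does not cover the projection ages.")
  rr_a <- if (is.data.frame(rr)) rr$rr[match(ages, rr$age)] else
    rep(rr, length(ages))
  if (anyNA(rr_a)) abort("`rr` does not cover the projection ages.")
  m <- expand_rate_table(mortality, ages, "mortality")
  h_d <- rr_a * l0
  h <- h_d + m
  if (any(h_d < 0) || any(m < 0)) abort("Negative hazard.")
  S <- exp(-c(0, cumsum(h[-length(h)])))
  frac <- ifelse(h > 0, h_d / h, 0)
  100 * sum(S * (1 - exp(-h)) * frac)
}

#' Difference in absolute risks with a bootstrap z-test
#'
#' Point difference `risk_ref - risk_exposed` (e.g. non-users minus users of
#' hormone therapy, so a protective exposure yields a positive difference).
#' When paired bootstrap replicate vectors are supplied, the standard error
#' is the SD of the replicate differences and the p-value the two-sided
#' normal tail of `difference / SE`.
#'
#' @param risk_ref,risk_exposed Point estimates in percent.
#' @param boot_ref,boot_exposed Optional paired bootstrap replicates (equal
#'   length, from the same resamples).
#' @return One-row tibble: `difference`, `se`, `statistic`, `p.value` (the
#'   latter three `NA` without replicates; a zero bootstrap SE is flagged as
#'   degenerate with a warning).
#' @export
#' @examples
#' risk_difference(6.1, 3.7)$difference  # 2.4
risk_difference <- function(risk_ref, risk_exposed,
                            boot_ref = NULL, boot_exposed = NULL) {
  d <- risk_ref - risk_exposed
  se <- stat <- p <- NA_real_
  if (!is.null(boot_ref) || !is.null(boot_exposed)) {
    if (length(boot_ref) != length(boot_exposed))
      abort("Bootstrap replicate vectors must have equal length (paired).")
    se <- sd(boot_ref - boot_exposed)
    if (se == 0) {
      warn("Degenerate bootstrap: zero SE for the risk difference.")
    } else {
      stat <- d / se
      p <- 2 * pnorm(-abs(stat))
    }
  }
  tibble::tibble(difference = d, se = se, statistic = stat, p.value = p)
}

#' Stratified bootstrap of a risk pipeline
#'
#' Resamples subjects with replacement within case and control strata,
#' re-runs `risk_fun` on each resample, and summarizes replicate spread.
#' Replicates on which `risk_fun` fails (e.g. an empty profile cell after
#' resampling) are dropped and counted; more than `max_drop` dropped
#' replicates is an error.
#'
#' @param data Analysis tibble containing `case_status`.
#' @param risk_fun Function taking a resampled tibble and returning a named
#'   numeric vector of risks.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Integer seed; replicates are drawn from named sub-streams so
#'   results are reproducible.
#' @param max_drop Maximum tolerated fraction of failed replicates.
#' @return List with `replicates` (kept replicates x profiles matrix),
#'   `n_dropped`, and `B`.
#' @export
bootstrap_risks <- function(data, risk_fun, B = 100, seed = 1L,
                            max_drop = 0.2) {
  if (B < 2) abort("At least 2 bootstrap replicates are required.")
  cases <- which(data$case_status == 1)
  ctrls <- which(data$case_status == 0)
  set.seed(substream_seed(seed, "bootstrap"))
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- c(sample(cases, length(cases), replace = TRUE),
             sample(ctrls, length(ctrls), replace = TRUE))
    reps[[b]] <- tryCatch(risk_fun(data[idx, , drop = FALSE]),
                          error = function(e) NULL)
  }
  ok <- !vapply(reps, is.null, logical(1))
  n_dropped <- sum(!ok)
  if (n_dropped > max_drop * B)
    abort(sprintf("%d of %d bootstrap replicates failed (> %.0f%% allowed).",
                  n_dropped, B, 100 * max_drop))
  if (n_dropped > 0)
    inform(sprintf("Dropped %d of %d bootstrap replicates.", n_dropped, B))
  list(replicates = do.call(rbind, reps[ok]), n_dropped = n_dropped, B = B)
}

# Point-estimate engine: age-group cell fits -> profile RRs and APs ->
# baseline hazard -> per-profile cumulative risk (percent).
compute_profile_risks <- function(data, incidence, mortality,
                                  exposure = "any",
                                  age_breaks = c(60, 70),
                                  age_start = 50, age_end = 80,
                                  covariates = c("age", "bmi", "study",
                                                 "pc1", "pc2", "pc3")) {
  prep <- prepare_cell_data(data, exposure, covariates)
  d <- prep$data
  bands <- tibble::tibble(
    age_start = c(age_start, age_breaks + 1),
    age_end = c(age_breaks + 1, age_end))
  grp <- findInterval(d$age, bands$age_start)
  grp[d$age < age_start] <- 1L  # ages below the horizon inform the first band
  profiles <- prep$cell_levels

  rr_by_group <- ap <- vector("list", nrow(bands))
  for (g in seq_len(nrow(bands))) {
    dg <- d[grp == g, , drop = FALSE]
    fit <- fit_cell_model(dg, exposure = exposure, covariates = covariates)
    rr <- exp(c(0, unname(coef(fit$fit)[paste0("cell", profiles[-1])])))
    names(rr) <- profiles
    rr_by_group[[g]] <- rr
    cases_g <- as.character(dg$cell[dg$case_status == 1])
    ap[[g]] <- attributable_proportion(cases_g, rr)
  }
  ap_tbl <- dplyr::mutate(bands, ap = unlist(ap))
  lambda0 <- baseline_hazard(incidence, ap_tbl,
                             ages = seq(age_start, age_end - 1))
  ages <- seq(age_start, age_end - 1)
  grp_age <- findInterval(ages, bands$age_start)
  risks <- vapply(profiles, function(p) {
    rr_a <- tibble::tibble(
      age = ages,
      rr = vapply(grp_age, function(g) rr_by_group[[g]][[p]], numeric(1)))
    cumulative_risk(rr_a, lambda0, mortality, age_start, age_end)
  }, numeric(1))
  risks
}

#' 30-year absolute risk by PRS quartile and exposure, with bootstrap CIs
#'
#' End-to-end projection: within each age group (by default at most 60,
#' 61-70, over 70), fits the adjusted quartile-by-exposure cell model to
#' obtain age-group relative risks (odds ratios taken as risk-ratio
#' approximations) and case-distribution attributable proportions; combines
#' them with external composite incidence to obtain the baseline hazard;
#' projects the cumulative risk of each of the 8 profiles from `age_start`
#' to `age_end` accounting for competing mortality; and bootstraps the whole
#' pipeline (stratified resampling of cases and controls) for confidence
#' intervals.
#'
#' @inheritParams fit_cell_model
#' @param incidence,mortality Banded rate tables (`age_start`, `age_end`,
#'   `rate_per_100k`), e.g. registry extracts read with [read_rate_table()]
#'   or simulated with [simulate_rate_tables()].
#' @param age_breaks Upper bounds of the lower age groups used for the
#'   age-specific relative risks.
#' @param age_start,age_end Projection interval.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Integer seed for the bootstrap.
#' @param ci_method `"normal"` (point +/- 1.96 x replicate SD, the default)
#'   or `"percentile"`.
#' @param conf_level Confidence level.
#' @return An `absrisk_table` tibble with one row per profile: `quartile`,
#'   `exposed`, `n_cases`, `n_controls`, `risk` (percent), `conf_low`,
#'   `conf_high`, `boot_se`; bootstrap replicates in `attr(, "replicates")`.
#'   Risk differences between exposure strata are available via
#'   [risk_difference_table()].
#' @export
absolute_risk_table <- function(data, incidence, mortality,
                                exposure = c("any", "eonly", "ep"),
                                age_breaks = c(60, 70),
                                age_start = 50, age_end = 80,
                                B = 100, seed = 1L,
                                ci_method = c("normal", "percentile"),
                                conf_level = 0.95,
                                covariates = c("age", "bmi", "study",
                                               "pc1", "pc2", "pc3")) {
  ci_method <- match.arg(ci_method)
  exposure <- exposure[1]
  prep <- prepare_cell_data(data, exposure, covariates)
  risk_fun <- function(d) compute_profile_risks(
    d, incidence, mortality, exposure = exposure, age_breaks = age_breaks,
    age_start = age_start, age_end = age_end, covariates = covariates)
  point <- risk_fun(data)
  boot <- bootstrap_risks(prep$data, risk_fun, B = B, seed = seed)
  z <- -qnorm_half(conf_level)
  bse <- apply(boot$replicates, 2, sd)
  if (ci_method == "normal") {
    lo <- pmax(point - z * bse, 0)
    hi <- pmin(point + z * bse, 100)
  } else {
    qs <- apply(boot$replicates, 2, quantile,
                probs = c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                type = 7)
    lo <- qs[1, ]; hi <- qs[2, ]
  }
  counts <- dplyr::count(prep$data, .data$cell, .data$case_status)
  counts <- tidyr::pivot_wider(counts, names_from = "case_status",
                               values_from = "n", values_fill = 0L)
  profiles <- names(point)
  out <- tibble::tibble(
    profile = profiles,
    quartile = as.integer(sub("Q(\\d)_.*", "\\1", profiles)),
    exposed = as.integer(grepl("_exposed$", profiles)),
    n_cases = counts$`1`[match(profiles, as.character(counts$cell))],
    n_controls = counts$`0`[match(profiles, as.character(counts$cell))],
    risk = unname(point),
    conf_low = unname(lo), conf_high = unname(hi),
    boot_se = unname(bse))
  structure(out,
            replicates = boot$replicates, n_dropped = boot$n_dropped,
            B = B, seed = seed, exposure = prep$exposure_name,
            ci_method = ci_method,
            class = c("absrisk_table", class(tibble::tibble())))
}

#' Risk differences between exposure strata per quartile
#'
#' For each PRS quartile, the difference in projected absolute risk between
#' the unexposed and exposed profile (positive when exposure is protective),
#' with a bootstrap z-test from the paired replicates of
#' [absolute_risk_table()].
#'
#' @param table An `absrisk_table`.
#' @return Tibble with one row per quartile: `quartile`, `risk_unexposed`,
#'   `risk_exposed`, `difference`, `se`, `p.value`.
#' @export
risk_difference_table <- function(table) {
  stopifnot(inherits(table, "absrisk_table"))
  reps <- attr(table, "replicates")
  purrr::map_dfr(sort(unique(table$quartile)), function(k) {
    p0 <- sprintf("Q%d_unexposed", k)
    p1 <- sprintf("Q%d_exposed", k)
    r0 <- table$risk[table$profile == p0]
    r1 <- table$risk[table$profile == p1]
    rd <- risk_difference(r0, r1, reps[, p0], reps[, p1])
    tibble::tibble(quartile = k, risk_unexposed = r0, risk_exposed = r1,
                   difference = rd$difference, se = rd$se,
                   p.value = rd$p.value)
  })
}
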