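# Small simulation worlds shared across tests.

# A fast config: few variants, cohort-scale prevalence so that fits on the
# full simulated population are well conditioned.
quick_config <- function(n = 4000, n_variants = 20, seed = 101, ...) {
  sim_config(n_population = n, n_variants = n_variants,
             baseline_prevalence = 0.30,
             n_cases = min(200, n %/% 4), n_controls = min(200, n %/% 4),
             seed = seed, ...)
}

# Simulated analysis table: phenotypes joined with quartiles from the
# package's own PRS path.
sim_analysis_data <- function(cfg, basis = "all") {
  pop <- simulate_population(cfg)
  prs <- compute_prs(pop$genotypes, pop$weights)
  q <- assign_quartiles(prs, pop$phenotypes, basis = basis)
  list(data = dplyr::inner_join(pop$phenotypes,
                                q[, c("subject_id", "prs_q")],
                                by = "subject_id"),
       pop = pop)
}

# Interaction increments giving exact exp-scale additivity
# (OR_k1 = OR_k0 + OR_01 - 1) for given main effects.
additive_increments <- function(quartile_or, exposure_or) {
  log(quartile_or + exposure_or - 1) - log(quartile_or) - log(exposure_or)
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
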