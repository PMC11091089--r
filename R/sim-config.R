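#' Simulation configuration for synthetic case-control data
#'
#' Builds and validates the configuration driving [simulate_population()].
#' Defaults emulate the pooled consortium study the package's analysis is
#' designed for: 141 biallelic risk variants (minor allele frequency at least
#' 1%), a multi-study case-control structure with roughly 11,519 cases and
#' 16,967 controls, any-MHT prevalence of 35.2%, and a quartile-by-exposure
#' disease model whose default cell odds ratios are 1.42 / 1.94 / 2.82 for PRS
#' quartiles 2-4 among non-users, 0.75 for hormone-therapy use in quartile 1,
#' and 1.09 / 1.40 / 1.83 for users in quartiles 2-4 (a sub-multiplicative,
#' sub-additive interaction pattern).
#'
#' The disease model is logistic:
#' \deqn{\mathrm{logit}\, P(D=1) = \alpha + \alpha_s + \beta_{kq} +
#'   \beta_a (age - \bar a) + \beta_b (BMI - \bar b) + \sum_j \gamma_j PC_j}
#' where \eqn{\beta_{kq}} is the log-OR of the (PRS quartile k, exposure q)
#' cell relative to (quartile 1, unexposed), and quartiles are defined by the
#' population quantiles of the true PRS. Hormone-therapy exposure is assigned
#' independently of genotype unless `gene_env_cor` is nonzero.
#'
#' @param n_population Number of subjects in the simulated source population.
#' @param n_variants Number of biallelic risk variants.
#' @param maf_range Length-2 numeric, allele-frequency range; must lie within
#'   `[0.01, 0.5]`.
#' @param weight_mean,weight_sd Mean and SD of per-variant log-OR weights
#'   (typical GWAS-scale effects).
#' @param n_studies Number of contributing studies.
#' @param study_intercepts Per-study log-odds offsets (length `n_studies`,
#'   centered by default).
#' @param study_props Sampling proportions per study (default equal).
#' @param mht_prevalence Probability of any-MHT use.
#' @param mht_type_split Named probabilities `c(eonly = , ep = )` of
#'   estrogen-only and combined estrogen-progestogen use among users; the
#'   remainder are users of other/unclassified regimens, excluded from
#'   type-specific analyses. Defaults derived from the printed analysis
#'   sample sizes of the emulated study.
#' @param type_reference_missing Fraction of never-users whose regimen-type
#'   reference information is missing completely at random, so that the three
#'   exposure analyses have different complete-case sample sizes.
#' @param age_mean,age_sd,bmi_mean,bmi_sd,pc_sd Covariate distribution
#'   parameters (years, kg/m2, unitless).
#' @param beta_age,beta_bmi,beta_pc True covariate log-ORs (`beta_pc` length 3).
#' @param quartile_logor Length-3 log-ORs for quartiles 2-4 among the
#'   unexposed.
#' @param true_mht_logor Log-OR of exposure within quartile 1.
#' @param true_interaction Length-3 product-term log-OR increments for
#'   quartiles 2-4; `c(0, 0, 0)` gives exact multiplicativity.
#' @param baseline_prevalence Disease probability in the reference cell at
#'   mean covariates; anchors the model intercept.
#' @param gene_env_cor Gene-environment dependence knob: log-odds shift in
#'   exposure probability per SD of PRS (0 = independence, the standard
#'   case-control assumption).
#' @param n_cases,n_controls Default counts drawn by [sample_case_control()].
#' @param seed Master seed; stage-specific sub-streams are derived from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_population()], [sample_case_control()],
#'   [simulate_rate_tables()]
#' @export
#' @examples
#' cfg <- sim_config(n_population = 2000, n_variants = 20,
#'                   n_cases = 300, n_controls = 300)
#' cfg$true_interaction
sim_config <- function(n_population = 300000,
                       n_variants = 141,
                       maf_range = c(0.01, 0.5),
                       weight_mean = 0.08,
                       weight_sd = 0.04,
                       n_studies = 4,
                       study_intercepts = NULL,
                       study_props = NULL,
                       mht_prevalence = 0.352,
                       mht_type_split = c(eonly = 0.215, ep = 0.150),
                       type_reference_missing = 0.70,
                       age_mean = 62, age_sd = 8,
                       bmi_mean = 27, bmi_sd = 5,
                       pc_sd = 1,
                       beta_age = 0.02,
                       beta_bmi = 0.02,
                       beta_pc = c(0, 0, 0),
                       quartile_logor = log(c(1.42, 1.94, 2.82)),
                       true_mht_logor = log(0.75),
                       true_interaction = log(c(1.09, 1.40, 1.83)) -
                         log(c(1.42, 1.94, 2.82)) - log(0.75),
                       baseline_prevalence = 0.05,
                       gene_env_cor = 0,
                       n_cases = 11519,
                       n_controls = 16967,
                       seed = 1L) {
  stopifnot(length(maf_range) == 2, length(quartile_logor) == 3,
            length(true_interaction) == 3, length(beta_pc) == 3)
  if (maf_range[1] < 0.01 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    abort("`maf_range` must be increasing and lie within [0.01, 0.5].")
  for (p in c(mht_prevalence, baseline_prevalence))
    if (p <= 0 || p >= 1)
      abort("Probabilities must lie strictly in (0, 1).")
  if (any(mht_type_split < 0) || sum(mht_type_split) > 1)
    abort("`mht_type_split` entries must be non-negative and sum to at most 1.")
  if (!all(c("eonly", "ep") %in% names(mht_type_split)))
    abort("`mht_type_split` must have names 'eonly' and 'ep'.")
  if (type_reference_missing < 0 || type_reference_missing >= 1)
    abort("`type_reference_missing` must be in [0, 1).")
  if (n_variants < 1 || n_studies < 1)
    abort("`n_variants` and `n_studies` must be positive.")
  if (n_cases + n_controls > n_population)
    abort("`n_cases + n_controls` cannot exceed `n_population`.")
  if (is.null(study_intercepts)) {
    study_intercepts <- if (n_studies == 1) 0 else {
      x <- seq(-0.15, 0.15, length.out = n_studies)
      x - mean(x)
    }
  }
  if (length(study_intercepts) != n_studies)
    abort("`study_intercepts` must have length `n_studies`.")
  if (is.null(study_props)) study_props <- rep(1 / n_studies, n_studies)
  if (length(study_props) != n_studies || any(study_props <= 0))
    abort("`study_props` must be positive with length `n_studies`.")
  study_props <- study_props / sum(study_props)

  structure(
    list(n_population = as.integer(n_population),
         n_variants = as.integer(n_variants),
         maf_range = maf_range,
         weight_mean = weight_mean, weight_sd = weight_sd,
         n_studies = as.integer(n_studies),
         study_intercepts = study_intercepts,
         study_props = study_props,
         mht_prevalence = mht_prevalence,
         mht_type_split = mht_type_split,
         type_reference_missing = type_reference_missing,
         age_mean = age_mean, age_sd = age_sd,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd, pc_sd = pc_sd,
         beta_age = beta_age, beta_bmi = beta_bmi, beta_pc = beta_pc,
         quartile_logor = quartile_logor,
         true_mht_logor = true_mht_logor,
         true_interaction = true_interaction,
         baseline_prevalence = baseline_prevalence,
         gene_env_cor = gene_env_cor,
         n_cases = as.integer(n_cases),
         n_controls = as.integer(n_controls),
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  population:", x$n_population, "subjects,", x$n_variants, "variants,",
      x$n_studies, "studies\n")
  cat("  exposure prevalence:", x$mht_prevalence, "\n")
  cat("  cell ORs (Q2-Q4, unexposed):",
      paste(round(exp(x$quartile_logor), 2), collapse = "/"), "\n")
  cat("  exposure OR in Q1:", round(exp(x$true_mht_logor), 2),
      "; interaction increments:",
      paste(round(x$true_interaction, 3), collapse = ", "), "\n")
  invisible(x)
}
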