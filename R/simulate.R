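#' Simulate a source population with known gene-environment structure
#'
#' Draws genotypes under Hardy-Weinberg equilibrium (per-variant
#' `Binomial(2, MAF)` dosages), builds the true weighted PRS, assigns
#' population-quantile PRS quartiles, assigns hormone-therapy exposure
#' (independent of genotype unless `gene_env_cor` is set), and generates
#' disease status from a logistic model whose quartile-by-exposure cell
#' log-odds ratios are recorded as ground truth.
#'
#' Estrogen-only and combined estrogen-progestogen use are mutually
#' exclusive sub-types of any-MHT use; non-users of any MHT are the common
#' reference for all three exposure variables. Users of other regimens and
#' never-users with missing type information carry `NA` in the type-specific
#' columns, so complete-case sample sizes differ across the three exposures,
#' as in real pooled analyses.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{genotypes}{tibble, `subject_id` plus one dosage column per variant.}
#'     \item{phenotypes}{tibble with `subject_id`, `case_status`, `age`, `bmi`,
#'       `study`, `pc1`-`pc3`, `mht_any`, `mht_eonly`, `mht_ep`, and the true
#'       quartile `prs_q_true`.}
#'     \item{weights}{tibble weight table for the simulated variants
#'       (see [read_weight_table()] for the column contract).}
#'     \item{truth}{a `truth_record` list: `cell_logor` (4x2 matrix, reference
#'       cell 0), `cell_or`, `reri_true` (OR-scale RERI per quartile 2-4),
#'       `log_additive_increments` (product-term log-ORs; all zero means exact
#'       multiplicativity), `quartile_cutpoints`, covariate effects, study
#'       intercepts, MAFs and weights.}
#'   }
#' @export
#' @examples
#' pop <- simulate_population(sim_config(n_population = 1000, n_variants = 10,
#'                                       n_cases = 100, n_controls = 100))
#' pop$truth$cell_or
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_population
  m <- config$n_variants

  set.seed(substream_seed(config$seed, "variants"))
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  if (any(maf <= 0 | maf >= 1))
    abort("Degenerate minor allele frequency (0 or 1) is not allowed.")
  weights <- rnorm(m, config$weight_mean, config$weight_sd)
  variant_id <- sprintf("rs%06d", seq_len(m))
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, m, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), character(1))

  set.seed(substream_seed(config$seed, "genotypes"))
  G <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)
  colnames(G) <- variant_id

  set.seed(substream_seed(config$seed, "covariates"))
  age <- rnorm(n, config$age_mean, config$age_sd)
  bmi <- rnorm(n, config$bmi_mean, config$bmi_sd)
  pcs <- matrix(rnorm(n * 3, 0, config$pc_sd), ncol = 3)
  study <- sample(paste0("study", seq_len(config$n_studies)), n,
                  replace = TRUE, prob = config$study_props)

  prs <- as.vector(G %*% weights)
  cut <- quantile(prs, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (any(diff(cut) <= 0))
    abort("True PRS quartile cut points are tied; increase variant weights.")
  q <- findInterval(prs, cut, left.open = TRUE) + 1L  # 1..4

  set.seed(substream_seed(config$seed, "exposure"))
  lp_mht <- qlogis(config$mht_prevalence)
  if (config$gene_env_cor != 0)
    lp_mht <- lp_mht + config$gene_env_cor * scale(prs)[, 1]
  mht_any <- rbinom(n, 1L, plogis(lp_mht))
  p_split <- config$mht_type_split
  type <- rep(NA_character_, n)
  users <- which(mht_any == 1L)
  type[users] <- sample(c("eonly", "ep", "other"), length(users),
                        replace = TRUE,
                        prob = c(p_split[["eonly"]], p_split[["ep"]],
                                 1 - sum(p_split)))
  # Type-specific variables: 1 for users of that type, 0 for never-users with
  # type reference information, NA otherwise (other-regimen users; MCAR
  # missingness among never-users).
  nonusers <- which(mht_any == 0L)
  ref_known <- rbinom(length(nonusers), 1L,
                      1 - config$type_reference_missing) == 1L
  mht_eonly <- rep(NA_integer_, n)
  mht_ep <- rep(NA_integer_, n)
  mht_eonly[users] <- ifelse(type[users] == "eonly", 1L, NA_integer_)
  mht_ep[users] <- ifelse(type[users] == "ep", 1L, NA_integer_)
  mht_eonly[nonusers[ref_known]] <- 0L
  mht_ep[nonusers[ref_known]] <- 0L

  # Disease model: cell effects on the true quartile x any-MHT grid.
  cell_logor <- matrix(0, nrow = 4, ncol = 2,
                       dimnames = list(paste0("Q", 1:4),
                                       c("unexposed", "exposed")))
  cell_logor[2:4, 1] <- config$quartile_logor
  cell_logor[1, 2] <- config$true_mht_logor
  cell_logor[2:4, 2] <- config$quartile_logor + config$true_mht_logor +
    config$true_interaction
  alpha <- qlogis(config$baseline_prevalence)
  study_idx <- as.integer(factor(study, levels = paste0("study",
                                                        seq_len(config$n_studies))))
  lp <- alpha + config$study_intercepts[study_idx] +
    cell_logor[cbind(q, mht_any + 1L)] +
    config$beta_age * (age - config$age_mean) +
    config$beta_bmi * (bmi - config$bmi_mean) +
    pcs %*% config$beta_pc

  set.seed(substream_seed(config$seed, "disease"))
  case_status <- rbinom(n, 1L, plogis(as.vector(lp)))

  subject_id <- sprintf("S%06d", seq_len(n))
  genotypes <- tibble::as_tibble(G)
  genotypes <- dplyr::bind_cols(tibble::tibble(subject_id = subject_id),
                                genotypes)
  phenotypes <- tibble::tibble(
    subject_id = subject_id,
    case_status = case_status,
    age = age, bmi = bmi, study = study,
    pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3],
    mht_any = mht_any, mht_eonly = mht_eonly, mht_ep = mht_ep,
    prs_q_true = q)
  weight_tbl <- tibble::tibble(
    variant_id = variant_id,
    chrom = as.character(rep_len(1:22, m)),
    pos = 10000L + 100L * seq_len(m),
    effect_allele = unname(ea), other_allele = unname(oa),
    weight = weights)

  cell_or <- exp(cell_logor)
  truth <- structure(list(
    cell_logor = cell_logor,
    cell_or = cell_or,
    reri_true = setNames(
      cell_or[2:4, 2] - cell_or[2:4, 1] - cell_or[1, 2] + 1,
      paste0("Q", 2:4)),
    log_additive_increments = setNames(config$true_interaction,
                                       paste0("Q", 2:4)),
    quartile_cutpoints = cut,
    beta_age = config$beta_age, beta_bmi = config$beta_bmi,
    beta_pc = config$beta_pc,
    study_intercepts = config$study_intercepts,
    maf = setNames(maf, variant_id),
    weights = setNames(weights, variant_id)), class = "truth_record")

  list(genotypes = genotypes, phenotypes = phenotypes,
       weights = weight_tbl, truth = truth)
}

#' Draw a case-control sample from a simulated population
#'
#' Simple random sampling without replacement within outcome strata
#' (retrospective sampling; odds ratios are preserved, with the sampling
#' fractions absorbed into the intercept).
#'
#' @param population The list returned by [simulate_population()].
#' @param n_cases,n_controls Numbers of cases and non-cases to draw.
#' @param seed Integer seed for the draw.
#' @return A list with `genotypes` and `phenotypes` tibbles restricted to the
#'   sampled subjects.
#' @export
sample_case_control <- function(population, n_cases, n_controls, seed = 1L) {
  ph <- population$phenotypes
  cases <- which(ph$case_status == 1L)
  ctrls <- which(ph$case_status == 0L)
  if (length(cases) < n_cases)
    abort(sprintf("Requested %d cases but the population contains only %d.",
                  n_cases, length(cases)))
  if (length(ctrls) < n_controls)
    abort(sprintf("Requested %d controls but the population contains only %d.",
                  n_controls, length(ctrls)))
  set.seed(substream_seed(seed, "case-control"))
  keep <- sort(c(sample(cases, n_cases), sample(ctrls, n_controls)))
  list(genotypes = population$genotypes[keep, , drop = FALSE],
       phenotypes = ph[keep, , drop = FALSE])
}

#' Simulate age-banded incidence and competing-mortality rate tables
#'
#' Stands in for registry rate extracts (disease incidence and non-disease
#' mortality for the projection ages). Rates grow geometrically across bands,
#' emulating the age pattern of colorectal cancer incidence and all-cause
#' non-CRC mortality in postmenopausal women; defaults give an age-50 CRC
#' incidence of 60 per 100,000 person-years roughly doubling by the mid-70s,
#' and non-CRC mortality from 300 to around 3,000 per 100,000.
#'
#' @param age_start,age_end Projection age range (must cover 50-80).
#' @param band_width Width of the age bands in years.
#' @param incidence50,mortality50 Rates (per 100,000 person-years) in the
#'   first band.
#' @param incidence_growth,mortality_growth Multiplicative growth per band;
#'   1 gives constant rates.
#' @return A list with `incidence` and `mortality` tibbles, each with columns
#'   `age_start`, `age_end` (closed-open bands) and `rate_per_100k`.
#' @export
#' @examples
#' rt <- simulate_rate_tables()
#' rt$incidence
simulate_rate_tables <- function(age_start = 50, age_end = 80, band_width = 5,
                                 incidence50 = 60, incidence_growth = 1.28,
                                 mortality50 = 300, mortality_growth = 1.58) {
  if (age_start > 50 || age_end < 80)
    abort("Rate tables must cover ages 50-80.")
  starts <- seq(age_start, age_end - band_width, by = band_width)
  band <- function(base, growth) {
    r <- base * growth^(seq_along(starts) - 1)
    if (any(r < 0)) abort("Negative rates are not allowed.")
    tibble::tibble(age_start = starts, age_end = starts + band_width,
                   rate_per_100k = r)
  }
  if (incidence50 < 0 || mortality50 < 0)
    abort("Negative rates are not allowed.")
  list(incidence = band(incidence50, incidence_growth),
       mortality = band(mortality50, mortality_growth))
}
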