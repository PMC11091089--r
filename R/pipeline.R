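#' Configuration for an end-to-end analysis run
#'
#' Validates input paths and collects the knobs of [run_all()]: quartile
#' basis, exposure set, bootstrap size and seed, age banding and output
#' directory. The seed is recorded in every output.
#'
#' @param genotypes,weights,phenotypes,incidence,mortality Input file paths
#'   (formats as in [read_genotypes()], [read_weight_table()],
#'   [read_phenotypes()], [read_rate_table()]).
#' @param out_dir Output directory (created if absent).
#' @param quartile_basis `"controls"` (default) or `"all"`.
#' @param exposures Exposure variables to analyze on the OR/interaction
#'   surface.
#' @param absrisk_exposures Exposures for which the absolute-risk projection
#'   is run (defaults to `"any"`; type-specific projections need large
#'   complete-case samples in every age group).
#' @param bootstrap_B Bootstrap replicates for absolute-risk CIs.
#' @param seed Master seed.
#' @param age_breaks Upper bounds of the lower age groups.
#' @param drop_ambiguous Drop strand-ambiguous variants when aligning
#'   VCF-derived genotypes.
#' @param verbose Emit progress/log messages.
#' @return A `run_config` list.
#' @export
run_config <- function(genotypes, weights, phenotypes, incidence, mortality,
                       out_dir, quartile_basis = c("controls", "all"),
                       exposures = c("any", "eonly", "ep"),
                       absrisk_exposures = "any",
                       bootstrap_B = 100, seed = 1L,
                       age_breaks = c(60, 70),
                       drop_ambiguous = FALSE, verbose = TRUE) {
  paths <- c(genotypes = genotypes, weights = weights,
             phenotypes = phenotypes, incidence = incidence,
             mortality = mortality)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    abort(paste0("Input file(s) not found: ",
                 paste(missing, collapse = ", ")))
  structure(list(paths = as.list(paths), out_dir = out_dir,
                 quartile_basis = match.arg(quartile_basis),
                 exposures = exposures,
                 absrisk_exposures = absrisk_exposures,
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed), age_breaks = age_breaks,
                 drop_ambiguous = drop_ambiguous, verbose = verbose),
            class = "run_config")
}

#' Load and validate all pipeline inputs
#'
#' @param config A [run_config()].
#' @return List with `genotypes`, `weights`, `phenotypes`, `incidence`,
#'   `mortality`; errors on malformed files or subject-id mismatches between
#'   genotypes and phenotypes (listing examples).
#' @export
load_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  weights <- read_weight_table(config$paths$weights)
  phenotypes <- read_phenotypes(config$paths$phenotypes)
  genotypes <- read_genotypes(config$paths$genotypes,
                              phenotypes = phenotypes)
  incidence <- read_rate_table(config$paths$incidence)
  mortality <- read_rate_table(config$paths$mortality)
  only_g <- setdiff(genotypes$subject_id, phenotypes$subject_id)
  only_p <- setdiff(phenotypes$subject_id, genotypes$subject_id)
  if (length(only_g) || length(only_p))
    abort(paste0(
      "Subject ids differ between genotypes and phenotypes. ",
      "Genotype-only examples: ",
      paste(head(only_g, 3), collapse = ", "),
      "; phenotype-only examples: ",
      paste(head(only_p, 3), collapse = ", ")))
  md <- attr(genotypes, "variant_metadata")
  if (!is.null(md))
    weights <- align_weights(weights, md,
                             drop_ambiguous = config$drop_ambiguous)
  list(genotypes = genotypes, weights = weights, phenotypes = phenotypes,
       incidence = incidence, mortality = mortality)
}

#' Run the full joint-association, interaction and absolute-risk pipeline
#'
#' Computes the PRS and quartiles, fits the adjusted quartile-by-exposure
#' cell model per exposure variable, derives joint and stratified OR grids,
#' trend tests, study heterogeneity, the multiplicative likelihood-ratio
#' test and Delta-method RERI, projects 30-year absolute risks with
#' bootstrap CIs, and writes:
#' \itemize{
#'   \item `prs.tsv` — per-subject PRS and quartile;
#'   \item `or_table_<exposure>.tsv` — joint/stratified ORs, RERI, trend and
#'     interaction p-values (estimates rounded to 2 decimals);
#'   \item `absolute_risk_<exposure>.tsv` — projected risks, CIs and
#'     user-versus-non-user differences;
#'   \item `interaction.json` — full-precision coefficients, covariances,
#'     RERI and LRT results;
#'   \item `run.log` — seed, sample counts, exclusion counts.
#' }
#' Outputs are deterministic given the seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every fitted object and result table.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("quartile basis: %s", config$quartile_basis))
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (config$verbose) inform(msg)
  }
  inputs <- load_inputs(config)
  say("loaded %d subjects, %d variants, %d weight rows",
      nrow(inputs$phenotypes),
      ncol(inputs$genotypes) - 1L, nrow(inputs$weights))
  if (!is.null(attr(inputs$weights, "prs_offset")))
    say("allele alignment: %d flipped, %d ambiguous",
        sum(inputs$weights$flipped %||% FALSE),
        sum(inputs$weights$ambiguous %||% FALSE))

  prs <- compute_prs(inputs$genotypes, inputs$weights)
  quart <- assign_quartiles(prs, inputs$phenotypes,
                            basis = config$quartile_basis)
  readr::write_tsv(quart, file.path(config$out_dir, "prs.tsv"))
  data <- dplyr::inner_join(inputs$phenotypes,
                            quart[, c("subject_id", "prs_q")],
                            by = "subject_id")

  results <- list(prs = quart)
  interaction_json <- list(seed = config$seed)
  for (expo in config$exposures) {
    exp_col <- paste0("mht_", expo)
    n_cc <- sum(!is.na(data[[exp_col]]))
    if (n_cc == 0 || length(unique(stats::na.omit(data[[exp_col]]))) < 2)
      abort(paste0("Exposure `", expo,
                   "` has no usable (non-missing, two-level) data."))
    say("exposure %s: %d complete-case subjects (%d excluded)",
        expo, n_cc, nrow(data) - n_cc)
    fit <- fit_cell_model(data, exposure = expo)
    grid <- joint_or_table(fit)
    strat <- stratified_or(grid)
    trends <- dplyr::bind_rows(trend_test(data, expo, 0),
                               trend_test(data, expo, 1))
    models <- fit_interaction_models(data, exposure = expo)
    lrt <- multiplicative_lrt(models$full, models$reduced)
    reri <- reri_inference(fit)
    het <- study_heterogeneity(data, expo)
    write_or_table(grid, strat, trends, lrt, reri, het,
                   file.path(config$out_dir,
                             paste0("or_table_", expo, ".tsv")), expo)
    results[[paste0("fit_", expo)]] <- fit
    results[[paste0("or_", expo)]] <- grid
    results[[paste0("reri_", expo)]] <- reri
    results[[paste0("lrt_", expo)]] <- lrt
    cells <- fit$cell_levels[-1]
    interaction_json[[expo]] <- list(
      n = fit$n, n_cases = fit$n_cases,
      coefficients = as.list(coef(fit$fit)),
      cell_vcov = vcov(fit$fit)[paste0("cell", cells),
                                paste0("cell", cells)],
      lrt = as.list(lrt), reri = reri,
      trend = trends, heterogeneity = het)
  }

  for (expo in config$absrisk_exposures) {
    say("absolute risk (%s): B = %d bootstrap replicates",
        expo, config$bootstrap_B)
    art <- absolute_risk_table(
      data, inputs$incidence, inputs$mortality, exposure = expo,
      age_breaks = config$age_breaks, B = config$bootstrap_B,
      seed = substream_seed(config$seed, paste0("absrisk-", expo)))
    diffs <- risk_difference_table(art)
    write_absrisk_table(art, diffs,
                        file.path(config$out_dir,
                                  paste0("absolute_risk_", expo, ".tsv")),
                        expo)
    results[[paste0("absrisk_", expo)]] <- art
    results[[paste0("riskdiff_", expo)]] <- diffs
  }

  jsonlite::write_json(interaction_json,
                       file.path(config$out_dir, "interaction.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(results)
}

# Per-study exposure log-ORs pooled with Cochran's Q; studies whose fit
# fails or lacks both exposure levels are skipped (counted in the output).
study_heterogeneity <- function(data, exposure,
                                covariates = c("age", "bmi",
                                               "pc1", "pc2", "pc3")) {
  exp_col <- paste0("mht_", exposure)
  d <- data[!is.na(data[[exp_col]]), , drop = FALSE]
  ests <- ses <- numeric(0)
  skipped <- 0L
  for (s in sort(unique(d$study))) {
    ds <- d[d$study == s, , drop = FALSE]
    if (length(unique(ds[[exp_col]])) < 2 ||
        length(unique(ds$case_status)) < 2) {
      skipped <- skipped + 1L
      next
    }
    covs <- Filter(function(cv) length(unique(ds[[cv]])) > 1, covariates)
    fml <- as.formula(paste("case_status ~", exp_col,
                            if (length(covs))
                              paste("+", paste(covs, collapse = " + "))
                            else ""))
    fit <- tryCatch(glm(fml, binomial(), data = ds,
                        control = list(epsilon = 1e-8, maxit = 100)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      skipped <- skipped + 1L
      next
    }
    ests <- c(ests, coef(fit)[[exp_col]])
    ses <- c(ses, sqrt(vcov(fit)[exp_col, exp_col]))
  }
  if (length(ests) < 2)
    return(tibble::tibble(q = NA_real_, df = NA_integer_,
                          p.value = NA_real_, pooled = NA_real_,
                          pooled_se = NA_real_, n_studies = length(ests),
                          n_skipped = skipped))
  dplyr::mutate(cochran_q(ests, ses), n_skipped = skipped)
}

fmt2 <- function(x) sprintf("%.2f", x)
fmtp <- function(p) ifelse(is.na(p), "NA", format(signif(p, 3)))

write_or_table <- function(grid, strat, trends, lrt, reri, het, path,
                           exposure) {
  rows <- list(
    tibble::tibble(exposure = exposure, quantity = "joint_or",
                   quartile = grid$quartile, stratum = grid$exposed,
                   estimate = fmt2(grid$or),
                   conf_low = fmt2(grid$conf_low),
                   conf_high = fmt2(grid$conf_high), p_value = "NA"),
    tibble::tibble(exposure = exposure,
                   quantity = ifelse(
                     strat$contrast == "exposure_within_quartile",
                     "or_exposure_within_quartile",
                     "or_quartile_within_stratum"),
                   quartile = strat$quartile, stratum = strat$stratum,
                   estimate = fmt2(strat$or),
                   conf_low = fmt2(strat$conf_low),
                   conf_high = fmt2(strat$conf_high), p_value = "NA"),
    tibble::tibble(exposure = exposure, quantity = "reri",
                   quartile = reri$quartile, stratum = NA_integer_,
                   estimate = fmt2(reri$reri),
                   conf_low = fmt2(reri$conf_low),
                   conf_high = fmt2(reri$conf_high),
                   p_value = fmtp(reri$p.value)),
    tibble::tibble(exposure = exposure, quantity = "trend",
                   quartile = NA_integer_, stratum = trends$stratum,
                   estimate = fmt2(exp(trends$estimate)),
                   conf_low = "NA", conf_high = "NA",
                   p_value = fmtp(trends$p.value)),
    tibble::tibble(exposure = exposure, quantity = "multiplicative_lrt",
                   quartile = NA_integer_, stratum = NA_integer_,
                   estimate = fmt2(lrt$statistic),
                   conf_low = "NA", conf_high = "NA",
                   p_value = fmtp(lrt$p.value)),
    tibble::tibble(exposure = exposure, quantity = "heterogeneity_q",
                   quartile = NA_integer_, stratum = NA_integer_,
                   estimate = ifelse(is.na(het$q), "NA", fmt2(het$q)),
                   conf_low = "NA", conf_high = "NA",
                   p_value = fmtp(het$p.value)))
  readr::write_tsv(dplyr::bind_rows(rows), path)
  invisible(path)
}

write_absrisk_table <- function(art, diffs, path, exposure) {
  main <- tibble::tibble(
    exposure = exposure, quartile = art$quartile,
    row = ifelse(art$exposed == 1, "exposed", "unexposed"),
    n_cases = as.character(art$n_cases),
    n_controls = as.character(art$n_controls),
    risk = fmt2(art$risk), conf_low = fmt2(art$conf_low),
    conf_high = fmt2(art$conf_high), p_value = "NA")
  dd <- tibble::tibble(
    exposure = exposure, quartile = diffs$quartile, row = "difference",
    n_cases = "NA", n_controls = "NA",
    risk = fmt2(diffs$difference), conf_low = "NA", conf_high = "NA",
    p_value = fmtp(diffs$p.value))
  readr::write_tsv(dplyr::bind_rows(main, dd), path)
  invisible(path)
}
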