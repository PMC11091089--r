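#' Fit the covariate-adjusted quartile-by-exposure cell model
#'
#' Fits one maximum-likelihood logistic regression of case status on a
#' 7-level dummy encoding of the non-reference (PRS quartile x exposure)
#' cells, adjusted for age (linear), BMI (linear), study (unordered dummies)
#' and the first three principal components, using (quartile 1, unexposed)
#' as the reference cell. Subjects with missing exposure are excluded
#' (complete-case per exposure variable, so the three hormone-therapy
#' analyses have different sample sizes).
#'
#' @param data Tibble containing `case_status`, `prs_q` (integer 1-4, e.g.
#'   from [assign_quartiles()] joined to the phenotypes), the exposure column,
#'   and the adjustment covariates `age`, `bmi`, `study`, `pc1`-`pc3`.
#' @param exposure One of `"any"`, `"eonly"`, `"ep"`; selects the
#'   `mht_<exposure>` column. Alternatively the name of any 0/1 column in
#'   `data`.
#' @param covariates Character vector of adjustment covariates; zero-variance
#'   covariates are dropped automatically (with a message) so that fits on
#'   covariate-free simulations are exactly covariate-free.
#' @return An object of class `cell_fit`: the glm fit plus metadata. Methods:
#'   [tidy()], [glance()], `coef()`, `vcov()`, `logLik()`.
#' @export
fit_cell_model <- function(data, exposure = c("any", "eonly", "ep"),
                           covariates = c("age", "bmi", "study",
                                          "pc1", "pc2", "pc3")) {
  prep <- prepare_cell_data(data, exposure, covariates)
  fml <- as.formula(paste("case_status ~ cell",
                          if (length(prep$covariates))
                            paste("+", paste(prep$covariates, collapse = " + "))
                          else ""))
  fit <- glm(fml, family = binomial(),
             data = prep$data,
             control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged)
    abort("Cell model did not converge within 100 iterations.")
  cell_coefs <- coef(fit)[paste0("cell", prep$cell_levels[-1])]
  if (anyNA(cell_coefs) || any(abs(cell_coefs) > 15)) {
    bad <- prep$cell_levels[-1][is.na(cell_coefs) | abs(cell_coefs) > 15]
    abort(paste0("Separation or unidentifiable cell coefficient(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(fit = fit,
                 exposure = prep$exposure_name,
                 cell_levels = prep$cell_levels,
                 covariates = prep$covariates,
                 n = nrow(prep$data),
                 n_cases = sum(prep$data$case_status == 1)),
            class = "cell_fit")
}

# Shared data preparation: complete-case subset, cell factor, covariate
# screening, per-cell case/control checks.
prepare_cell_data <- function(data, exposure, covariates,
                              require_cells = TRUE) {
  exposure <- exposure[1]
  exp_col <- if (exposure %in% c("any", "eonly", "ep"))
    paste0("mht_", exposure) else exposure
  if (!exp_col %in% names(data))
    abort(paste0("Exposure column `", exp_col, "` not found in the data."))
  need <- c("case_status", "prs_q", exp_col)
  if (!all(need %in% names(data)))
    abort(paste0("Data must contain columns: ", paste(need, collapse = ", ")))
  d <- data[!is.na(data[[exp_col]]), , drop = FALSE]
  if (!nrow(d)) abort("No subjects with non-missing exposure.")
  if (!all(d[[exp_col]] %in% c(0, 1)))
    abort("Exposure must be coded 0/1.")
  if (!all(d$prs_q %in% 1:4)) abort("`prs_q` must take values in 1..4.")

  cell_levels <- paste0("Q", rep(1:4, each = 2), "_",
                        rep(c("unexposed", "exposed"), 4))
  cell <- factor(paste0("Q", d$prs_q, "_",
                        ifelse(d[[exp_col]] == 1, "exposed", "unexposed")),
                 levels = cell_levels)
  if (require_cells) {
    tab <- table(cell, factor(d$case_status, levels = 0:1))
    empty <- rownames(tab)[rowSums(tab) == 0]
    if (length(empty))
      abort(paste0("Empty quartile-by-exposure cell(s): ",
                   paste(empty, collapse = ", ")))
    onesided <- rownames(tab)[tab[, 1] == 0 | tab[, 2] == 0]
    if (length(onesided))
      abort(paste0("Cell(s) with no cases or no controls (separation): ",
                   paste(onesided, collapse = ", ")))
  }
  d$cell <- droplevels(cell)

  keep <- character(0)
  for (cv in intersect(covariates, names(d))) {
    x <- d[[cv]]
    if (length(unique(x)) > 1) keep <- c(keep, cv) else
      inform(paste0("Covariate `", cv, "` is constant; dropped."))
  }
  if (length(miss <- setdiff(covariates, names(d))))
    abort(paste0("Missing covariate column(s): ", paste(miss, collapse = ", ")))
  if ("study" %in% keep) d$study <- factor(d$study)
  list(data = d, covariates = keep, cell_levels = levels(d$cell),
       exposure_name = exp_col)
}

#' @export
coef.cell_fit <- function(object, ...) coef(object$fit)

#' @export
vcov.cell_fit <- function(object, ...) vcov(object$fit)

#' @export
logLik.cell_fit <- function(object, ...) logLik(object$fit)

#' @export
print.cell_fit <- function(x, ...) {
  cat("<cell_fit> quartile x", x$exposure, "logistic model\n")
  cat("  n =", x$n, "(", x$n_cases, "cases ), covariates:",
      paste(x$covariates, collapse = ", "), "\n")
  print(joint_or_table(x))
  invisible(x)
}

#' @rdname fit_cell_model
#' @param x,object A `cell_fit`.
#' @param ... Unused.
#' @export
tidy.cell_fit <- function(x, ...) {
  est <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se),
                 statistic = unname(est / se),
                 p.value = 2 * pnorm(-abs(unname(est / se))))
}

#' @rdname fit_cell_model
#' @export
glance.cell_fit <- function(x, ...) {
  tibble::tibble(logLik = as.numeric(logLik(x$fit)),
                 df = length(coef(x$fit)),
                 n = x$n, n_cases = x$n_cases,
                 converged = x$fit$converged)
}

#' Joint odds-ratio grid of the cell model
#'
#' Exponentiates the 7 non-reference cell coefficients into a 4x2 grid of
#' odds ratios relative to (quartile 1, unexposed), with Wald 95% confidence
#' intervals \eqn{\exp(\beta \pm 1.96\,SE)}. The covariance of the cell
#' log-ORs is carried as an attribute for downstream Delta-method inference.
#'
#' @param fit A `cell_fit` from [fit_cell_model()].
#' @param conf_level Confidence level (default 0.95).
#' @return A `joint_or_table` tibble with columns `quartile`, `exposed`,
#'   `log_or`, `se`, `or`, `conf_low`, `conf_high` (reference cell OR fixed
#'   at 1), with the full 8x8 cell log-OR covariance (zero rows for the
#'   reference) in `attr(, "vcov")`.
#' @export
joint_or_table <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "cell_fit"))
  z <- -qnorm_half(conf_level)
  cells <- fit$cell_levels
  coef_names <- paste0("cell", cells[-1])
  beta <- c(0, unname(coef(fit$fit)[coef_names]))
  V <- matrix(0, length(cells), length(cells),
              dimnames = list(cells, cells))
  V[-1, -1] <- vcov(fit$fit)[coef_names, coef_names]
  se <- sqrt(diag(V))
  grid <- tibble::tibble(
    quartile = as.integer(sub("Q(\\d)_.*", "\\1", cells)),
    exposed = as.integer(grepl("_exposed$", cells)),
    log_or = beta,
    se = ifelse(seq_along(cells) == 1, NA_real_, se),
    or = exp(beta),
    conf_low = ifelse(seq_along(cells) == 1, NA_real_, exp(beta - z * se)),
    conf_high = ifelse(seq_along(cells) == 1, NA_real_, exp(beta + z * se)))
  new_joint_or_table(grid, V, exposure = fit$exposure)
}

qnorm_half <- function(conf_level) stats::qnorm((1 - conf_level) / 2)

new_joint_or_table <- function(grid, V, exposure = NA_character_) {
  structure(grid, vcov = V, exposure = exposure,
            class = c("joint_or_table", class(tibble::tibble())))
}

#' Build a joint OR table from externally supplied odds ratios
#'
#' Useful for working with published OR grids when the underlying fit (and
#' hence the coefficient covariance) is unavailable; Delta-method standard
#' errors of derived contrasts are then `NA`.
#'
#' @param grid Tibble with columns `quartile` (1-4), `exposed` (0/1) and `or`;
#'   the (1, 0) cell must have OR 1.
#' @param vcov Optional 8x8 covariance of the cell log-ORs, rows/columns in
#'   grid order with zeros for the reference cell.
#' @return A `joint_or_table`.
#' @export
#' @examples
#' grid <- tidyr::expand_grid(quartile = 1:4, exposed = 0:1)
#' grid$or <- c(1, 0.75, 1.42, 1.09, 1.94, 1.40, 2.82, 1.83)
#' stratified_or(as_joint_or_table(grid))
as_joint_or_table <- function(grid, vcov = NULL) {
  stopifnot(all(c("quartile", "exposed", "or") %in% names(grid)))
  grid <- dplyr::arrange(tibble::as_tibble(grid), .data$quartile,
                         .data$exposed)
  if (nrow(grid) != 8 || !isTRUE(all.equal(grid$or[1], 1)))
    abort("Need all 8 cells with reference cell (Q1, unexposed) OR = 1.")
  if (any(grid$or <= 0)) abort("Odds ratios must be positive.")
  grid$log_or <- log(grid$or)
  if (is.null(vcov)) vcov <- matrix(NA_real_, 8, 8) else
    stopifnot(identical(dim(vcov), c(8L, 8L)))
  if (!"se" %in% names(grid)) grid$se <- sqrt(diag(vcov))
  new_joint_or_table(grid, vcov)
}

#' Stratified odds ratios derived from the joint cell grid
#'
#' From the saturated quartile-by-exposure grid, forms (i) the within-quartile
#' OR of exposure, \eqn{OR_{k1}/OR_{k0}}, and (ii) the within-exposure-stratum
#' OR of each quartile versus quartile 1, \eqn{OR_{kq}/OR_{1q}}. Standard
#' errors use the Delta method on the log scale with the cell covariance
#' (exactly, since the contrasts are linear in the cell log-ORs).
#'
#' @param table A `joint_or_table`.
#' @param conf_level Confidence level.
#' @return A tibble with columns `contrast` (`"exposure_within_quartile"` or
#'   `"quartile_within_stratum"`), `quartile`, `stratum`, `or`, `conf_low`,
#'   `conf_high`, `se_log`.
#' @export
stratified_or <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "joint_or_table"))
  V <- attr(table, "vcov")
  z <- -qnorm_half(conf_level)
  idx <- function(k, q) which(table$quartile == k & table$exposed == q)
  one <- function(contrast, k, stratum, i, j) {
    lo <- table$log_or[i] - table$log_or[j]
    v <- V[i, i] + V[j, j] - 2 * V[i, j]
    se <- sqrt(v)
    tibble::tibble(contrast = contrast, quartile = k, stratum = stratum,
                   or = exp(lo),
                   conf_low = exp(lo - z * se), conf_high = exp(lo + z * se),
                   se_log = se)
  }
  rows <- list()
  for (k in 1:4)
    rows <- c(rows, list(one("exposure_within_quartile", k, NA_integer_,
                             idx(k, 1), idx(k, 0))))
  for (q in 0:1) for (k in 2:4)
    rows <- c(rows, list(one("quartile_within_stratum", k, q,
                             idx(k, q), idx(1, q))))
  dplyr::bind_rows(rows)
}

#' Wald trend test across PRS quartiles within an exposure stratum
#'
#' Refits the adjusted logistic model on the stratum with the ordinal
#' quartile entered as a single numeric covariate (values 1-4) and tests its
#' coefficient with a two-sided Wald test.
#'
#' @inheritParams fit_cell_model
#' @param stratum Exposure value defining the stratum (0 or 1).
#' @return One-row tibble: `stratum`, `estimate` (per-quartile log-OR),
#'   `std.error`, `statistic`, `p.value`, `n`.
#' @export
trend_test <- function(data, exposure = c("any", "eonly", "ep"), stratum,
                       covariates = c("age", "bmi", "study",
                                      "pc1", "pc2", "pc3")) {
  stopifnot(stratum %in% c(0, 1))
  prep <- prepare_cell_data(data, exposure, covariates, require_cells = FALSE)
  d <- prep$data[prep$data[[prep$exposure_name]] == stratum, , drop = FALSE]
  if (!all(1:4 %in% d$prs_q))
    abort("All four PRS quartiles must be represented in the stratum.")
  covs <- Filter(function(cv) length(unique(d[[cv]])) > 1, prep$covariates)
  if ("study" %in% covs) d$study <- droplevels(d$study)
  fml <- as.formula(paste("case_status ~ prs_q",
                          if (length(covs))
                            paste("+", paste(covs, collapse = " + ")) else ""))
  fit <- glm(fml, family = binomial(), data = d,
             control = list(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) abort("Trend model did not converge.")
  b <- coef(fit)[["prs_q"]]
  se <- sqrt(vcov(fit)["prs_q", "prs_q"])
  zstat <- b / se
  tibble::tibble(stratum = stratum, estimate = b, std.error = se,
                 statistic = zstat, p.value = 2 * pnorm(-abs(zstat)),
                 n = nrow(d))
}

#' Cochran's Q heterogeneity test for study-specific estimates
#'
#' Fixed-effect inverse-variance pooling: with weights \eqn{w_s = 1/SE_s^2},
#' the pooled estimate is \eqn{\bar\theta = \sum w_s \theta_s / \sum w_s} and
#' \eqn{Q = \sum w_s (\theta_s - \bar\theta)^2} is referred to a chi-square
#' distribution with (number of studies - 1) degrees of freedom.
#'
#' @param estimates Per-study estimates (e.g. log-ORs).
#' @param ses Per-study standard errors (positive, finite).
#' @return One-row tibble: `q`, `df`, `p.value`, `pooled`, `pooled_se`,
#'   `n_studies`.
#' @export
#' @examples
#' cochran_q(c(0, 1), c(1, 1))  # Q = 0.5, df = 1
cochran_q <- function(estimates, ses) {
  if (length(estimates) != length(ses))
    abort("`estimates` and `ses` must have equal length.")
  if (length(estimates) < 2)
    abort("At least 2 studies are required.")
  if (any(!is.finite(ses)) || any(ses <= 0))
    abort("Standard errors must be positive and finite (zero SE not allowed).")
  w <- 1 / ses^2
  pooled <- sum(w * estimates) / sum(w)
  q <- sum(w * (estimates - pooled)^2)
  df <- length(estimates) - 1L
  tibble::tibble(q = q, df = df,
                 p.value = pchisq(q, df, lower.tail = FALSE),
                 pooled = pooled, pooled_se = sqrt(1 / sum(w)),
                 n_studies = length(estimates))
}
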