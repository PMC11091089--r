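#' Fit nested main-effect and product-term logistic models
#'
#' Parameterization for the multiplicative interaction test: the reduced
#' model has 3 quartile dummies plus the exposure main effect; the full model
#' adds the 3 quartile-by-exposure product terms. Adjustment covariates are
#' identical in both fits, and both use the same complete-case subjects.
#'
#' @inheritParams fit_cell_model
#' @return A list with `full` and `reduced` glm fits (classed `gxe_fit`),
#'   suitable for [multiplicative_lrt()].
#' @export
fit_interaction_models <- function(data, exposure = c("any", "eonly", "ep"),
                                   covariates = c("age", "bmi", "study",
                                                  "pc1", "pc2", "pc3")) {
  prep <- prepare_cell_data(data, exposure, covariates)
  d <- prep$data
  d$quartile <- factor(paste0("Q", d$prs_q), levels = paste0("Q", 1:4))
  d$exposure <- d[[prep$exposure_name]]
  cov_part <- if (length(prep$covariates))
    paste("+", paste(prep$covariates, collapse = " + ")) else ""
  ctl <- list(epsilon = 1e-8, maxit = 100)
  reduced <- glm(as.formula(paste("case_status ~ quartile + exposure",
                                  cov_part)),
                 family = binomial(), data = d, control = ctl)
  full <- glm(as.formula(paste(
    "case_status ~ quartile + exposure + quartile:exposure", cov_part)),
    family = binomial(), data = d, control = ctl)
  if (!reduced$converged || !full$converged)
    abort("Interaction model did not converge.")
  list(full = full, reduced = reduced, n = nrow(d),
       exposure = prep$exposure_name)
}

#' Likelihood ratio test for multiplicative interaction
#'
#' Twice the log-likelihood difference between the model with
#' quartile-by-exposure product terms and the nested main-effects model,
#' referred to a chi-square distribution with degrees of freedom equal to the
#' number of product terms (3 for quartiles x binary exposure).
#'
#' @param full,reduced Nested glm fits on identical subjects (e.g. from
#'   [fit_interaction_models()]); `reduced`'s terms must be a subset of
#'   `full`'s.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `n`.
#' @export
multiplicative_lrt <- function(full, reduced) {
  tf <- attr(full$terms, "term.labels")
  tr <- attr(reduced$terms, "term.labels")
  if (!all(tr %in% tf))
    abort("`reduced` must be nested within `full` (term sets differ).")
  if (stats::nobs(full) != stats::nobs(reduced))
    abort("Fits use different numbers of subjects; refit on common rows.")
  stat <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced)))
  if (stat < -1e-8)
    abort("Negative LRT statistic: models are not nested as claimed.")
  stat <- max(stat, 0)
  df <- length(coef(full)) - length(coef(reduced))
  tibble::tibble(statistic = stat, df = df,
                 p.value = if (df == 0) 1 else
                   pchisq(stat, df, lower.tail = FALSE),
                 n = stats::nobs(full))
}

#' Relative excess risk due to interaction (point estimate)
#'
#' The additive-scale interaction contrast
#' \deqn{RERI = OR_{11} - OR_{10} - OR_{01} + 1,}
#' where \eqn{OR_{11}} is the jointly exposed cell (quartile k, exposed),
#' \eqn{OR_{10}} the (quartile k, unexposed) cell and \eqn{OR_{01}} the
#' (quartile 1, exposed) cell, all relative to (quartile 1, unexposed).
#' Zero means the joint effect equals the sum of the two individual excess
#' risks; odds ratios are treated as risk-ratio approximations
#' (rare-disease assumption).
#'
#' @param or11,or10,or01 Positive odds ratios (vectorized).
#' @return Numeric RERI value(s).
#' @export
#' @examples
#' reri_point(1.83, 2.82, 0.75)  # -0.74
reri_point <- function(or11, or10, or01) {
  if (any(c(or11, or10, or01) <= 0))
    abort("Odds ratios must be positive.")
  or11 - or10 - or01 + 1
}

#' Delta-method inference for RERI per PRS quartile
#'
#' For each quartile k in 2..4, computes
#' \eqn{RERI_k = e^{\beta_{k1}} - e^{\beta_{k0}} - e^{\beta_{01}} + 1}
#' from the fitted cell coefficients, with variance
#' \eqn{g^\top \Sigma g} for gradient
#' \eqn{g = (e^{\beta_{k1}}, -e^{\beta_{k0}}, -e^{\beta_{01}})} and
#' \eqn{\Sigma} the corresponding coefficient covariance block. Confidence
#' intervals are \eqn{RERI \pm z_{1-\alpha/2} \sqrt{Var}} and the p-value is
#' the two-sided normal tail of \eqn{RERI/SE}.
#'
#' @param fit A `cell_fit` from [fit_cell_model()].
#' @param conf_level Confidence level.
#' @return A `reri_result` tibble with one row per quartile 2-4: `quartile`,
#'   `reri`, `variance`, `conf_low`, `conf_high`, `p.value`.
#' @export
reri_inference <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "cell_fit"))
  z <- -qnorm_half(conf_level)
  V <- vcov(fit$fit)
  b <- coef(fit$fit)
  out <- purrr::map_dfr(2:4, function(k) {
    nm <- c(paste0("cellQ", k, "_exposed"),
            paste0("cellQ", k, "_unexposed"),
            "cellQ1_exposed")
    if (!all(nm %in% names(b)))
      abort(paste0("Fit lacks cell coefficient(s): ",
                   paste(setdiff(nm, names(b)), collapse = ", ")))
    e <- exp(unname(b[nm]))
    reri <- e[1] - e[2] - e[3] + 1
    g <- c(e[1], -e[2], -e[3])
    v <- as.numeric(t(g) %*% V[nm, nm] %*% g)
    if (v < 0) abort("Negative Delta-method variance; covariance block invalid.")
    se <- sqrt(v)
    tibble::tibble(quartile = k, reri = reri, variance = v,
                   conf_low = reri - z * se, conf_high = reri + z * se,
                   p.value = if (se > 0) 2 * pnorm(-abs(reri / se))
                             else as.numeric(reri == 0))
  })
  class(out) <- c("reri_result", class(out))
  attr(out, "exposure") <- fit$exposure
  out
}
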