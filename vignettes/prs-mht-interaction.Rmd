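---
title: "Joint PRS and hormone-therapy analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint PRS and hormone-therapy analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsgxe)
library(dplyr)
```

# The scientific problem

Colorectal cancer (CRC) risk in postmenopausal women is shaped both by
common genetic variation — summarized here as a weighted polygenic risk
score (PRS) over GWAS-identified risk variants — and by menopausal hormone
therapy (MHT), which is protective on average. The question this package
addresses is whether those two factors *interact*: is the protection
conferred by MHT the same at every level of genetic risk, and if not, on
which scale does the departure appear?

Two scales matter and can disagree:

* **Multiplicative interaction** asks whether the odds ratio (OR) of MHT
  differs across PRS strata. It is tested by adding quartile-by-exposure
  product terms to a logistic model and comparing nested fits with a
  likelihood ratio test (LRT).
* **Additive interaction** asks whether the *excess risk* of the joint
  exposure departs from the sum of the individual excess risks. It is
  measured by the relative excess risk due to interaction,
  $$\mathrm{RERI} = OR_{11} - OR_{10} - OR_{01} + 1,$$
  where subscripts index (PRS stratum, exposure) relative to the doubly
  unexposed reference, and ORs stand in for relative risks under the
  rare-disease assumption. RERI = 0 means exact additivity. With a
  polygenic score the two scales can separate sharply: a constant OR for
  MHT across quartiles (no multiplicative interaction) still implies a much
  larger absolute risk reduction in the top quartile, i.e. a negative RERI.

Additive interaction is the public-health scale: it identifies the
subgroups in which an intervention prevents the most cases. The package
therefore also projects the **30-year absolute risk** of CRC from age 50
for each (PRS quartile, MHT) profile, combining the case-control estimates
with external age-specific incidence and competing non-CRC mortality.

# The analysis pipeline

## PRS and quartiles

The score is the weighted dosage sum $PRS_j = \sum_i w_i g_{ij}$ with
$w_i$ a prior log-OR weight and $g_{ij} \in [0,2]$ the effect-allele
dosage. `align_weights()` reconciles the weight table with the genotype
file's counted allele: a variant counted on the other allele contributes
$w(2-g) = -wg + 2w$, implemented by flipping the weight's sign and
accumulating the $2w$ constants into a bookkeeping offset, so reported
scores are identical to manual recoding. Strand-ambiguous (A/T, C/G)
variants are flagged because their orientation is unresolvable without
strand information; dropping them is a switch, not a default.

Quartile cut points are the 25/50/75th percentiles (R type-7, linear
interpolation between order statistics — chosen for bit-reproducibility)
of the **control** PRS distribution by default, with half-open intervals
$(-\infty,q_{25}], (q_{25},q_{50}], (q_{50},q_{75}], (q_{75},\infty)$ and
quartile 1 as referent. The source data's convention (controls vs pooled
vs per-study) is not documented anywhere we could rely on, so the basis is
an explicit option (`basis = "all"` for the pooled sample); the default
follows the usual case-control PRS convention. All-tied scores make
quartiles undefined and raise an error rather than an arbitrary split.

## The cell model

All estimation flows through one saturated logistic model with a 7-level
dummy encoding of the non-reference (quartile × exposure) cells, adjusted
for age (linear), BMI (linear), study (unordered dummies) and the first
three principal components (linear). Linearity is the minimal reading —
no functional form was documented — and the covariates enter identically
in every fit so that nested comparisons are valid. Convergence is declared
at a relative log-likelihood change below 1e-8 within 100 iterations;
non-convergence, empty cells and separation (a cell with no cases or no
controls) are hard errors naming the offending cell, never silent.

Because the model is saturated in the cells, the "within strata" rows of
the classical presentation are exact ratios of joint cells
(`stratified_or()`), and the main-effects + product-terms parameterization
used for the LRT (`fit_interaction_models()`) has identical likelihood and
fitted cells — both identities are enforced by tests. Trend tests refit
each exposure stratum with the quartile as a numeric 1–4 covariate (Wald);
fitting strata separately is again the minimal reading of an undocumented
choice. Heterogeneity across studies uses fixed-effect inverse-variance
pooling and Cochran's Q on per-study adjusted exposure log-ORs.

## RERI inference

`reri_inference()` evaluates RERI per quartile $k \in \{2,3,4\}$ from the
cell coefficients, with the Delta method: gradient
$g = (e^{\beta_{k1}}, -e^{\beta_{k0}}, -e^{\beta_{01}})$ and variance
$g^\top \Sigma g$ from the coefficient covariance block. CIs are
$\mathrm{RERI} \pm 1.96\,SE$ and the p-value the two-sided normal tail of
$\mathrm{RERI}/SE$ — the construction that reproduces the printed
CI ↔ p-value relation of the study this mirrors (a RERI of −0.74 with CI
(−1.00, −0.48) implies $SE \approx 0.133$ and $p \approx 2\times10^{-8}$).
The Delta variance is validated against a parametric bootstrap of the
coefficient vector in the tests. RERI uses ORs as risk-ratio
approximations; at case-control prevalences this is the standard reading
and is stated rather than hidden.

## Absolute risk projection

For each age group (≤60, 61–70, >70 — stratified refits of the cell
model, the minimal reading of "age-specific relative risks"), the model
supplies profile relative risks $RR_g(\text{profile})$ and the
case-distribution (Bruzzi) attributable proportion
$$AP_g = 1 - \frac{1}{n_{\text{cases}}}\sum_{\text{cases}}
\frac{1}{RR_g(\text{profile of case})},$$
which converts composite registry incidence $I(a)$ into the baseline
(referent-profile) hazard $\lambda_0(a) = I(a)(1-AP_{g(a)})$. The 30-year
risk of a profile is the discrete annual recursion
$$\text{risk} = \sum_{a=50}^{79} S(a)\,[1-e^{-h(a)}]\,
\frac{h_d(a)}{h(a)},\qquad
h_d = RR\,\lambda_0,\; h = h_d + m,\;
S(a{+}1) = S(a)e^{-h(a)},$$
with $m(a)$ the competing non-CRC mortality. Annual steps with
piecewise-constant hazards are the standard discrete approximation of the
continuous cause-specific formulation; in the constant-hazard,
no-competing-risk limit the recursion collapses to
$1 - e^{-\lambda_0 \cdot 30}$ exactly, and against a 2-million-individual
discrete-time microsimulation it agrees within Monte-Carlo error (both are
tests). Negative hazards and non-contiguous rate bands are errors.

Uncertainty comes from resampling subjects with replacement within case
and control strata and re-running the whole chain (age-group fits, APs,
hazards, projection) per replicate — 100 replicates by default, matching
the emulated study. CIs default to the normal approximation
(point ± 1.96 × replicate SD) because percentile intervals are unstable at
B = 100; `ci_method = "percentile"` is the switch. Replicates that lose a
profile cell are dropped and counted; more than 20% dropped aborts. The
user-vs-non-user risk difference is tested with a z-statistic from the
paired replicate differences; the source study's own difference test is
undocumented, so this choice is ours and is labelled as such.

# The synthetic world

`simulate_population()` generates the world the analysis assumes, with
recorded ground truth (`truth_record`) for recovery tests:

* genotypes: per-variant Binomial(2, MAF) under Hardy–Weinberg, MAF
  uniform on [0.01, 0.5] (mirroring the ≥1% MAF filter), 141 variants by
  default with N(0.08, 0.04) log-OR weights — GWAS-scale effects chosen
  once as realistic;
* disease: logistic in study offsets, centered age/BMI/PC effects and the
  (true-quartile × any-MHT) cell log-ORs. Default cells reproduce the
  emulated study's grid (1.42/1.94/2.82 for Q2–Q4 non-users, 0.75 for MHT
  in Q1, 1.09/1.40/1.83 for exposed Q2–Q4);
* exposure: any-MHT prevalence 35.2%, independent of genotype by default
  (the standard case-control assumption), with a `gene_env_cor` knob for
  robustness studies. Regimen types among users are split E-only 21.5% /
  E+P 15.0% / other 63.5% — derived from the emulated study's printed
  analysis counts — and are mutually exclusive; type reference information
  is missing completely at random for 70% of never-users, so the three
  exposure analyses have different complete-case sizes, as in the source.
  The printed counts identify the subset sizes but not the mechanism;
  MCAR is a deliberate simplification. The disease model applies cell
  effects through any-MHT only; regimen type is a label on top.
* rate tables: `simulate_rate_tables()` stands in for registry extracts
  (the real SEER series is external, versioned data and deliberately not
  reproduced); defaults grow CRC incidence from 60/100k person-years at
  50 by 1.28× per 5-year band and non-CRC female mortality from 300/100k
  by 1.58×, which puts 30-year risks in the 2–6% range the emulated study
  reports.

What a green recovery test does *not* establish: robustness to
study-specific quartile conventions, matched designs (matching is
deliberately replaced by covariate adjustment, since the pooled analysis
adjusts rather than conditions), informative missingness of exposure
type, genotyping/imputation error, or real registry rate structure.

Randomness is driven by one master seed with named sub-streams per stage
(`variants`, `genotypes`, `covariates`, `exposure`, `disease`,
`bootstrap`), so stages are independently reproducible.

# Numerical and degenerate-input policy

* Quartiles: type-7 percentiles; ties broken by interval membership;
  all-tied input errors.
* Logistic fits: `glm` ML, epsilon 1e-8, 100 iterations; separation and
  empty cells are named errors.
* LRT: statistic clipped at 0 with 1e-8 slack; equal models give
  statistic 0, p 1; non-nested or different-n fits error.
* RERI: exact reproduction of `reri_point` on the exponentiated
  coefficients; negative Delta variance (an invalid covariance block)
  errors.
* Projection: hazards must be non-negative; `h = 0` years contribute 0 by
  the limit convention; risks are clipped to [0, 100] only at the CI
  stage (points are bounded by construction).
* TSV outputs round to 2 decimals (presentation convention); JSON keeps
  full precision; rerunning with a fixed seed is byte-identical.

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_population = 40000, n_variants = 50,
                  n_cases = 2000, n_controls = 3000, seed = 7)
pop <- simulate_population(cfg)
cc <- sample_case_control(pop, 2000, 3000, seed = 7)

prs <- compute_prs(cc$genotypes, pop$weights)
quart <- assign_quartiles(prs, cc$phenotypes, basis = "controls")
d <- inner_join(cc$phenotypes, quart[, c("subject_id", "prs_q")],
                by = "subject_id")

fit <- fit_cell_model(d, exposure = "any")
joint_or_table(fit)
stratified_or(joint_or_table(fit))
reri_inference(fit)

models <- fit_interaction_models(d, "any")
multiplicative_lrt(models$full, models$reduced)

rates <- simulate_rate_tables()
risks <- absolute_risk_table(d, rates$incidence, rates$mortality,
                             exposure = "any", B = 100, seed = 7)
risk_difference_table(risks)
autoplot(risks)
```

# Known limitations

* Conditional logistic regression for matched sets is out of scope; so are
  random-effects meta-analysis, winner's-curse re-adjustment of weights,
  LD-aware score construction and cross-ancestry portability.
* RERI from ORs inherits the rare-disease approximation; at the simulated
  cohort prevalences used in calibration tests the OR-scale truth is used
  consistently, but users should not over-interpret RERI magnitudes when
  the outcome is common.
* Percentile bootstrap CIs at B = 100 are noisy; the normal approximation
  is the default for that reason, not because it is superior in general.
* The absolute-risk projection treats the relative risks as
  age-group-constant and the rate tables as exact; registry sampling error
  is not propagated.
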