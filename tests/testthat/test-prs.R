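test_that("compute_prs matches analytic values and a brute-force oracle", {
  g <- tibble::tibble(subject_id = c("a", "b"), rs1 = c(0, 2))
  w <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
                      other_allele = "G", weight = log(2))
  expect_equal(compute_prs(g, w)$prs, c(0, 2 * log(2)))

  set.seed(11)
  G <- matrix(rbinom(100, 2, 0.3), 10, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  gt <- dplyr::bind_cols(tibble::tibble(subject_id = paste0("s", 1:10)),
                         tibble::as_tibble(G))
  wt <- tibble::tibble(variant_id = paste0("v", 1:10),
                       effect_allele = "A", other_allele = "C",
                       weight = rnorm(10))
  # independent oracle: explicit double-loop accumulation
  oracle <- vapply(1:10, function(j) {
    s <- 0
    for (i in 1:10) s <- s + wt$weight[i] * G[j, i]
    s
  }, numeric(1))
  expect_equal(compute_prs(gt, wt)$prs, oracle)
})

test_that("PRS is invariant to variant ordering and linear in weights", {
  set.seed(12)
  G <- matrix(runif(60, 0, 2), 6, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  gt <- dplyr::bind_cols(tibble::tibble(subject_id = paste0("s", 1:6)),
                         tibble::as_tibble(G))
  wt <- tibble::tibble(variant_id = paste0("v", 1:10),
                       effect_allele = "A", other_allele = "C",
                       weight = rnorm(10))
  perm <- sample(10)
  expect_equal(compute_prs(gt, wt)$prs,
               compute_prs(gt[, c(1, 1 + perm)], wt[perm, ])$prs)
  w2 <- dplyr::mutate(wt, weight = 3 * weight)
  expect_equal(compute_prs(gt, w2)$prs, 3 * compute_prs(gt, wt)$prs)
})

test_that("compute_prs rejects bad inputs", {
  gt <- tibble::tibble(subject_id = "s1", v1 = 1)
  wt <- tibble::tibble(variant_id = "v2", effect_allele = "A",
                       other_allele = "C", weight = 1)
  expect_error(compute_prs(gt, wt), "lack variants")
  wt$variant_id <- "v1"
  gt$v1 <- 2.5
  expect_error(compute_prs(gt, wt), "\\[0, 2\\]")
})

test_that("quartile cut points use type-7 percentiles with half-open intervals", {
  # Controls with PRS 1..8: independent percentile computation gives
  # 2.75 / 4.5 / 6.25
  prs <- tibble::tibble(subject_id = paste0("s", 1:8), prs = as.numeric(1:8))
  ph <- tibble::tibble(subject_id = paste0("s", 1:8),
                       case_status = rep(0L, 8))
  q <- assign_quartiles(prs, ph, basis = "controls")
  expect_equal(attr(q, "cutpoints"),
               quantile(1:8, c(.25, .5, .75), type = 7, names = FALSE))
  expect_equal(q$prs_q, rep(1:4, each = 2))

  # a case below the minimum control lands in Q1
  prs2 <- dplyr::bind_rows(prs, tibble::tibble(subject_id = "c1", prs = -5))
  ph2 <- dplyr::bind_rows(ph, tibble::tibble(subject_id = "c1",
                                             case_status = 1L))
  q2 <- assign_quartiles(prs2, ph2, basis = "controls")
  expect_equal(q2$prs_q[q2$subject_id == "c1"], 1L)

  # translation invariance
  q3 <- assign_quartiles(dplyr::mutate(prs, prs = prs + 100), ph, "controls")
  expect_equal(q3$prs_q, q$prs_q)
})

test_that("quartiles are balanced on controls and scale-invariant in weights", {
  sim <- sim_analysis_data(quick_config(n = 2000, seed = 103),
                           basis = "controls")
  d <- sim$data
  ctrl <- d[d$case_status == 0, ]
  counts <- table(ctrl$prs_q)
  expect_length(counts, 4)
  expect_lte(max(counts) - min(counts), 2)

  w2 <- dplyr::mutate(sim$pop$weights, weight = weight * 2.5)
  q1 <- assign_quartiles(compute_prs(sim$pop$genotypes, sim$pop$weights),
                         sim$pop$phenotypes, "controls")
  q2 <- assign_quartiles(compute_prs(sim$pop$genotypes, w2),
                         sim$pop$phenotypes, "controls")
  expect_equal(q1$prs_q, q2$prs_q)
  expect_equal(q2$prs, 2.5 * q1$prs)
})

test_that("degenerate PRS inputs raise the tied-input error", {
  prs <- tibble::tibble(subject_id = paste0("s", 1:20), prs = rep(1, 20))
  ph <- tibble::tibble(subject_id = paste0("s", 1:20),
                       case_status = rep(0L, 20))
  expect_error(assign_quartiles(prs, ph), "tied")
  expect_error(assign_quartiles(prs[1:4, ], ph), "At least 8")
})

test_that("align_weights is identity when counted allele is the effect allele", {
  wt <- tibble::tibble(variant_id = c("v1", "v2"),
                       effect_allele = c("A", "C"),
                       other_allele = c("G", "T"),
                       weight = c(0.1, -0.2))
  md <- tibble::tibble(variant_id = c("v1", "v2"),
                       counted_allele = c("A", "C"),
                       other_allele = c("G", "T"))
  out <- align_weights(wt, md)
  expect_equal(out$weight, wt$weight)
  expect_false(any(out$flipped))
  expect_equal(attr(out, "prs_offset"), 0)
})

test_that("allele flips reflect dosages: PRS matches a manual recode oracle", {
  set.seed(14)
  n_var <- 20
  wt <- tibble::tibble(variant_id = paste0("v", 1:n_var),
                       effect_allele = rep("A", n_var),
                       other_allele = rep("G", n_var),
                       weight = rnorm(n_var, 0.1, 0.05))
  flip_idx <- c(2, 5, 9, 13, 20)
  md <- tibble::tibble(variant_id = wt$variant_id,
                       counted_allele = ifelse(seq_len(n_var) %in% flip_idx,
                                               "G", "A"),
                       other_allele = ifelse(seq_len(n_var) %in% flip_idx,
                                             "A", "G"))
  G <- matrix(rbinom(10 * n_var, 2, 0.4), 10, n_var,
              dimnames = list(NULL, wt$variant_id))
  gt <- dplyr::bind_cols(tibble::tibble(subject_id = paste0("s", 1:10)),
                         tibble::as_tibble(G))
  aligned <- align_weights(wt, md)
  got <- compute_prs(gt, aligned)$prs
  # oracle: manually recode flipped dosages to effect-allele counts
  G2 <- G
  G2[, flip_idx] <- 2 - G2[, flip_idx]
  oracle <- as.vector(G2 %*% wt$weight)
  expect_equal(got, oracle)

  # reflection symmetry at a single variant: dosage 2 on the counted other
  # allele contributes like dosage 0 on the effect-allele encoding
  one_w <- wt[2, ]
  one_md <- md[2, ]
  a2 <- align_weights(one_w, one_md)
  g_two <- tibble::tibble(subject_id = "x", v2 = 2)
  g_zero <- tibble::tibble(subject_id = "x", v2 = 0)
  expect_equal(compute_prs(g_two, a2)$prs, 0)
  expect_equal(compute_prs(g_zero, a2)$prs, 2 * one_w$weight)
})

test_that("align_weights flags ambiguity and errors on unmatched variants", {
  wt <- tibble::tibble(variant_id = c("v1", "v2"),
                       effect_allele = c("A", "A"),
                       other_allele = c("T", "G"),
                       weight = c(0.1, 0.2))
  md <- tibble::tibble(variant_id = c("v1", "v2"),
                       counted_allele = c("A", "A"),
                       other_allele = c("T", "G"))
  expect_warning(out <- align_weights(wt, md), "Strand-ambiguous")
  expect_true(out$ambiguous[1]); expect_false(out$ambiguous[2])
  expect_warning(dropped <- align_weights(wt, md, drop_ambiguous = TRUE))
  expect_equal(dropped$variant_id, "v2")

  expect_error(
    align_weights(wt, md[1, , drop = FALSE]),
    "v2")
})
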