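#' Align a variant weight table to a genotype file's counted allele
#'
#' Genotype dosages count copies of one allele per variant (the "counted"
#' allele, e.g. the ALT allele of a VCF). When the weight table's effect
#' allele is the *other* allele, the subject's effect-allele count is
#' `2 - dosage`; equivalently the weight sign is flipped and `2 * weight` is
#' added to a bookkeeping constant, which this function accumulates in the
#' `prs_offset` attribute consumed by [compute_prs()]. Strand-ambiguous
#' variants (A/T or C/G pairs), whose orientation cannot be resolved without
#' strand information, are flagged and optionally dropped.
#'
#' @param weights Weight table tibble with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `weight` (and optionally `chrom`, `pos`).
#' @param variant_metadata Per-variant metadata of the genotype source:
#'   columns `variant_id`, `counted_allele`, `other_allele` (and optionally
#'   `chrom`, `pos` for coordinate matching when ids do not match).
#' @param drop_ambiguous Drop strand-ambiguous variants (default `FALSE`,
#'   with a warning listing them).
#' @return The aligned weight table with logical columns `flipped` and
#'   `ambiguous`, and attribute `prs_offset` (a constant added to every PRS).
#' @export
align_weights <- function(weights, variant_metadata, drop_ambiguous = FALSE) {
  check_weight_table(weights)
  md <- variant_metadata
  stopifnot(all(c("variant_id", "counted_allele", "other_allele") %in%
                  names(md)))

  idx <- match(weights$variant_id, md$variant_id)
  if (anyNA(idx) && all(c("chrom", "pos") %in% names(weights)) &&
      all(c("chrom", "pos") %in% names(md))) {
    miss <- which(is.na(idx))
    key_w <- paste(weights$chrom[miss], weights$pos[miss])
    key_m <- paste(md$chrom, md$pos)
    idx[miss] <- match(key_w, key_m)
  }
  if (anyNA(idx))
    abort(paste0("Variants not found in the genotype source: ",
                 paste(weights$variant_id[is.na(idx)], collapse = ", ")))
  md <- md[idx, , drop = FALSE]

  same <- weights$effect_allele == md$counted_allele &
    weights$other_allele == md$other_allele
  flip <- weights$effect_allele == md$other_allele &
    weights$other_allele == md$counted_allele
  if (any(!same & !flip))
    abort(paste0("Allele mismatch for variants: ",
                 paste(weights$variant_id[!same & !flip], collapse = ", ")))

  pair <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ambiguous <- pair(weights$effect_allele, weights$other_allele) %in%
    c("A T", "C G")

  out <- weights
  out$flipped <- flip
  out$ambiguous <- ambiguous
  offset <- sum(2 * out$weight[flip])
  out$weight[flip] <- -out$weight[flip]

  if (any(ambiguous)) {
    warn(paste0("Strand-ambiguous variants (A/T or C/G): ",
                paste(out$variant_id[ambiguous], collapse = ", "),
                if (drop_ambiguous) " -- dropped." else " -- kept."))
    if (drop_ambiguous) {
      offset <- offset - sum(2 * weights$weight[flip & ambiguous])
      out <- out[!ambiguous, , drop = FALSE]
    }
  }
  attr(out, "prs_offset") <- offset
  out
}

#' Compute the weighted polygenic risk score
#'
#' The PRS of subject j is the weighted allele-dosage sum
#' \eqn{PRS_j = \sum_i w_i g_{ij}}, where \eqn{w_i} is the variant's log-OR
#' weight and \eqn{g_{ij} \in [0, 2]} the (possibly fractional, imputed)
#' effect-allele dosage. Any `prs_offset` attribute left by [align_weights()]
#' is added to every score.
#'
#' @param genotypes Tibble with `subject_id` and one numeric dosage column per
#'   variant; dosages must be in `[0, 2]` with no missing values (see
#'   [read_genotypes()] for load-time imputation of missing dosages).
#' @param weights Weight table covering exactly the variants to score.
#' @return A tibble with columns `subject_id` and `prs`.
#' @export
#' @examples
#' g <- tibble::tibble(subject_id = c("a", "b"), rs1 = c(0, 2))
#' w <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
#'                     other_allele = "G", weight = log(2))
#' compute_prs(g, w)
compute_prs <- function(genotypes, weights) {
  check_weight_table(weights)
  vcols <- setdiff(names(genotypes), "subject_id")
  missing_v <- setdiff(weights$variant_id, vcols)
  if (length(missing_v))
    abort(paste0("Genotypes lack variants in the weight table: ",
                 paste(head(missing_v, 10), collapse = ", ")))
  G <- as.matrix(genotypes[, weights$variant_id, drop = FALSE])
  if (anyNA(G))
    abort("Missing dosages; impute or filter at load time (see read_genotypes).")
  if (any(G < 0 | G > 2))
    abort("Dosages must lie in [0, 2].")
  offset <- attr(weights, "prs_offset") %||% 0
  tibble::tibble(subject_id = genotypes$subject_id,
                 prs = as.vector(G %*% weights$weight) + offset)
}

#' Assign PRS quartile categories
#'
#' Cut points are the 25th/50th/75th percentiles of the basis group's PRS
#' (linear interpolation between order statistics, R quantile type 7), with
#' half-open assignment intervals \eqn{(-\infty, q_{25}]}, \eqn{(q_{25},
#' q_{50}]}, \eqn{(q_{50}, q_{75}]}, \eqn{(q_{75}, \infty)}. Quartile 1 is
#' the reference category in all downstream models. The default basis is the
#' control group, the usual convention in case-control PRS analyses; `"all"`
#' uses the pooled sample.
#'
#' @param prs Tibble from [compute_prs()] (`subject_id`, `prs`).
#' @param phenotypes Phenotype tibble with `subject_id` and `case_status`;
#'   required when `basis = "controls"`.
#' @param basis `"controls"` or `"all"`.
#' @return A tibble with `subject_id`, `prs`, and integer `prs_q` in 1..4.
#' @export
assign_quartiles <- function(prs, phenotypes = NULL,
                             basis = c("controls", "all")) {
  basis <- match.arg(basis)
  stopifnot(all(c("subject_id", "prs") %in% names(prs)))
  if (!all(is.finite(prs$prs))) abort("PRS values must be finite.")
  if (basis == "controls") {
    if (is.null(phenotypes))
      abort("`phenotypes` is required when basis = 'controls'.")
    ctrl_ids <- phenotypes$subject_id[phenotypes$case_status == 0]
    base <- prs$prs[prs$subject_id %in% ctrl_ids]
  } else {
    base <- prs$prs
  }
  if (length(base) < 8)
    abort("At least 8 subjects are required in the quartile basis group.")
  if (length(unique(base)) == 1)
    abort("All PRS values in the basis group are tied; quartiles are undefined.")
  cut <- quantile(base, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (any(diff(cut) <= 0))
    abort("Tied PRS quartile cut points; quartiles are undefined.")
  q <- findInterval(prs$prs, cut, left.open = TRUE) + 1L
  out <- tibble::tibble(subject_id = prs$subject_id, prs = prs$prs,
                        prs_q = q)
  attr(out, "cutpoints") <- cut
  attr(out, "basis") <- basis
  out
}

check_weight_table <- function(weights) {
  need <- c("variant_id", "effect_allele", "other_allele", "weight")
  if (!all(need %in% names(weights)))
    abort(paste0("Weight table must have columns: ",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(weights$variant_id))
    abort("Duplicated variant_id in weight table.")
  if (any(weights$effect_allele == weights$other_allele))
    abort("effect_allele must differ from other_allele.")
  if (!all(is.finite(weights$weight)))
    abort("Weights must be finite.")
  invisible(weights)
}
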