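#' Read a variant weight table
#'
#' Tab-separated with header `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `weight` (log-odds ratio). Weights are consumed as given
#' (any winner's-curse adjustment is assumed to have been applied upstream).
#'
#' @param path Path to the TSV file.
#' @return A validated weight-table tibble.
#' @export
read_weight_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           variant_id = "c", chrom = "c", pos = "i",
                           effect_allele = "c", other_allele = "c",
                           weight = "d"))
  if (!nrow(tbl)) abort(paste0("Empty weight table: ", path))
  check_weight_table(tbl)
  tbl
}

#' Read a phenotype table
#'
#' Tab-separated with header `subject_id`, `case_status`, `age`, `bmi`,
#' `study`, `pc1`, `pc2`, `pc3`, `mht_any`, `mht_eonly`, `mht_ep`. The three
#' hormone-therapy variables are 0/1 with `NA` for missing; estrogen-only and
#' combined estrogen-progestogen use are mutually exclusive and imply any-MHT
#' use; never-users of any MHT are the common reference.
#'
#' @param path Path to the TSV file.
#' @return A validated phenotype tibble.
#' @export
read_phenotypes <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = "c", case_status = "i",
                           age = "d", bmi = "d", study = "c",
                           pc1 = "d", pc2 = "d", pc3 = "d",
                           mht_any = "i", mht_eonly = "i", mht_ep = "i"))
  if (!nrow(tbl)) abort(paste0("Empty phenotype table: ", path))
  validate_phenotypes(tbl)
}

#' Validate phenotype invariants
#'
#' @param tbl A phenotype tibble (see [read_phenotypes()] for the contract).
#' @return The tibble, invisibly usable in a pipe; errors name offending rows.
#' @export
validate_phenotypes <- function(tbl) {
  need <- c("subject_id", "case_status", "age", "bmi", "study",
            "pc1", "pc2", "pc3", "mht_any", "mht_eonly", "mht_ep")
  if (length(miss <- setdiff(need, names(tbl))))
    abort(paste0("Phenotype table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(tbl$subject_id)) abort("Duplicated subject_id.")
  if (!all(tbl$case_status %in% c(0, 1)))
    abort("case_status must be 0/1 with no missing values.")
  bad <- which(!is.na(tbl$mht_eonly) & !is.na(tbl$mht_ep) &
                 tbl$mht_eonly == 1 & tbl$mht_ep == 1)
  if (length(bad))
    abort(paste0("mht_eonly and mht_ep are mutually exclusive; both 1 at ",
                 "row(s): ", paste(head(bad, 5), collapse = ", ")))
  for (col in c("mht_eonly", "mht_ep")) {
    bad <- which(!is.na(tbl[[col]]) & tbl[[col]] == 1 & tbl$mht_any != 1)
    if (length(bad))
      abort(paste0("Subjects with ", col, " = 1 must have mht_any = 1; ",
                   "row(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  tbl
}

#' Read a genotype dosage matrix (TSV or VCF)
#'
#' TSV: header `subject_id` followed by one column per variant, entries are
#' effect-allele dosages in `[0, 2]` (fractional allowed). VCF (`.vcf`):
#' dosages are taken from the `DS` FORMAT field, falling back to hard-called
#' `GT` (count of ALT alleles); the counted allele is ALT, and per-variant
#' `variant_metadata` (for [align_weights()]) is attached as an attribute.
#'
#' Missing dosages are imputed at load time to twice the counted-allele
#' frequency estimated from non-missing subjects (controls only when
#' `phenotypes` is supplied), or rejected with `missing = "fail"`.
#'
#' @param path Path to a `.tsv`/`.txt` matrix or a `.vcf` file.
#' @param phenotypes Optional phenotype tibble used to restrict the
#'   allele-frequency estimate for imputation to controls.
#' @param missing `"impute"` (default) or `"fail"`.
#' @return Genotype tibble (`subject_id` + dosage columns); for VCF input the
#'   `variant_metadata` attribute holds `variant_id`, `chrom`, `pos`,
#'   `counted_allele`, `other_allele`.
#' @export
read_genotypes <- function(path, phenotypes = NULL,
                           missing = c("impute", "fail")) {
  missing <- match.arg(missing)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    geno <- read_genotypes_vcf(path)
  } else {
    geno <- readr::read_tsv(path, show_col_types = FALSE)
    if (!nrow(geno)) abort(paste0("Empty genotype file: ", path))
    if (names(geno)[1] != "subject_id")
      abort("First genotype column must be subject_id.")
  }
  vcols <- setdiff(names(geno), "subject_id")
  G <- as.matrix(geno[, vcols, drop = FALSE])
  if (!is.numeric(G)) abort("Dosages must be numeric.")
  if (anyNA(G)) {
    if (missing == "fail")
      abort("Missing dosages present and missing = 'fail'.")
    rows <- if (!is.null(phenotypes)) {
      geno$subject_id %in% phenotypes$subject_id[phenotypes$case_status == 0]
    } else rep(TRUE, nrow(G))
    for (j in which(colSums(is.na(G)) > 0)) {
      eaf <- mean(G[rows, j], na.rm = TRUE) / 2
      if (is.nan(eaf)) eaf <- mean(G[, j], na.rm = TRUE) / 2
      if (is.nan(eaf)) abort(paste0("Variant ", vcols[j], " entirely missing."))
      G[is.na(G[, j]), j] <- 2 * eaf
    }
  }
  if (any(G < 0 | G > 2)) abort("Dosages must lie in [0, 2].")
  out <- dplyr::bind_cols(tibble::tibble(subject_id = geno$subject_id),
                          tibble::as_tibble(G))
  attr(out, "variant_metadata") <- attr(geno, "variant_metadata")
  out
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    abort("Reading VCF requires the VariantAnnotation package.")
  vcf <- VariantAnnotation::readVcf(path)
  ids <- names(SummarizedExperiment::rowRanges(vcf))
  gmats <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gmats)) {
    D <- t(gmats$DS)  # samples x variants
    storage.mode(D) <- "double"
  } else if ("GT" %in% names(gmats)) {
    GT <- t(gmats$GT)
    D <- matrix(NA_real_, nrow(GT), ncol(GT), dimnames = dimnames(GT))
    D[] <- vapply(as.vector(GT), function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    }, numeric(1))
  } else {
    abort("VCF has neither a DS nor a GT FORMAT field.")
  }
  colnames(D) <- ids
  rr <- SummarizedExperiment::rowRanges(vcf)
  md <- tibble::tibble(
    variant_id = ids,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    counted_allele = as.character(unlist(rr$ALT)),
    other_allele = as.character(rr$REF))
  out <- dplyr::bind_cols(tibble::tibble(subject_id = rownames(D)),
                          tibble::as_tibble(D))
  attr(out, "variant_metadata") <- md
  out
}

#' Write a genotype matrix as TSV or minimal VCF
#'
#' The VCF writer emits VCFv4.2 with a `DS` FORMAT field (effect-allele
#' dosage) and `GT` hard calls rounded from the dosage; the counted (ALT)
#' allele of each variant is the weight table's effect allele.
#'
#' @param genotypes Genotype tibble (`subject_id` + dosage columns).
#' @param path Output path; `.vcf` selects the VCF writer.
#' @param metadata Variant metadata (`variant_id`, `chrom`, `pos`,
#'   `counted_allele`, `other_allele`); required for VCF output.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, metadata = NULL) {
  if (!grepl("\\.vcf$", path)) {
    readr::write_tsv(genotypes, path)
    return(invisible(path))
  }
  if (is.null(metadata))
    abort("VCF output requires `metadata` (variant coordinates and alleles).")
  vcols <- setdiff(names(genotypes), "subject_id")
  md <- metadata[match(vcols, metadata$variant_id), , drop = FALSE]
  if (anyNA(md$variant_id)) abort("Metadata missing for some variants.")
  G <- as.matrix(genotypes[, vcols, drop = FALSE])
  gt <- matrix(c("0/0", "0/1", "1/1")[pmin(pmax(round(G), 0), 2) + 1],
               nrow = nrow(G))
  body <- vapply(seq_along(vcols), function(j) {
    paste(c(md$chrom[j], md$pos[j], md$variant_id[j], md$other_allele[j],
            md$counted_allele[j], ".", "PASS", ".", "GT:DS",
            paste0(gt[, j], ":", format(G[, j], trim = TRUE, digits = 10))),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
           "Description=\"Estimated alternate allele dosage\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$subject_id), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an age-banded rate table
#'
#' Comma-separated with header `age_start`, `age_end`, `rate_per_100k`
#' (closed-open age bands; events per 100,000 person-years), the shape of a
#' registry rate export.
#'
#' @param path Path to the CSV file.
#' @return A rate tibble.
#' @export
read_rate_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           age_start = "d", age_end = "d",
                           rate_per_100k = "d"))
  if (!nrow(tbl)) abort(paste0("Empty rate table: ", path))
  if (any(tbl$rate_per_100k < 0)) abort("Negative rates are not allowed.")
  if (any(tbl$age_end <= tbl$age_start))
    abort("age_end must exceed age_start.")
  dplyr::arrange(tbl, .data$age_start)
}

#' Write a rate table as CSV
#' @param tbl Rate tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}
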