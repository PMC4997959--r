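#' Per-variant association scan under one or more genetic models
#'
#' The full single-cohort pipeline: variant QC (MAF and imputation
#' quality), model-specific genotype coding, the coded-category
#' frequency filter, then the mixed-model score test for every passing
#' variant under every requested model, reusing one polygenic null fit.
#'
#' @param genotypes A `genotype_matrix`.
#' @param phenotypes Prepared phenotype tibble (after
#'   [apply_exclusions()]); samples are intersected with the genotypes
#'   and must overlap.
#' @param kinship Optional `kinship_matrix`; estimated from `genotypes`
#'   when `NULL`. Subset to the analysis samples either way.
#' @param models Character subset of additive/dominant/recessive.
#' @param maf_min,info_min Variant QC thresholds (see [variant_qc()]).
#' @param coded_freq_bounds Length-2 bounds for the coded-category
#'   filter.
#' @param recessive_coding Passed to the per-variant coding (see
#'   [code_genotype()]).
#' @param standardize Z-standardise the response (see [build_design()]).
#' @param fit Optional pre-computed [fit_polygenic()] for these samples;
#'   fitted here when `NULL`.
#' @return A `gwas_scan` tibble, one row per variant x model:
#'   `snp, chrom, pos, a0, a1, model, beta, se, p, n, coded_freq, info`.
#'   Untestable codes (no variance after adjustment) keep their row with
#'   `NA` statistics. Deterministic order: variants in input order within
#'   model.
#' @export
run_scan <- function(genotypes, phenotypes, kinship = NULL,
                     models = c("additive", "dominant", "recessive"),
                     maf_min = 0.01, info_min = 0.4,
                     coded_freq_bounds = c(0.01, 0.99),
                     recessive_coding = c("gp", "hardcall"),
                     standardize = FALSE, fit = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  recessive_coding <- match.arg(recessive_coding)
  keep <- intersect(phenotypes$sample, genotypes$samples)
  if (length(keep) < 3) stop("fewer than 3 overlapping samples", call. = FALSE)
  phenotypes <- phenotypes[match(keep, phenotypes$sample), , drop = FALSE]
  genotypes <- subset_genotypes(genotypes, samples = keep)
  if (is.null(kinship)) {
    kinship <- estimate_kinship(genotypes)
  } else if (!identical(kinship$samples, keep)) {
    idx <- match(keep, kinship$samples)
    if (anyNA(idx)) stop("kinship is missing analysis samples", call. = FALSE)
    kinship <- structure(list(samples = keep, K = kinship$K[idx, idx],
                              n_variants = kinship$n_variants),
                         class = "kinship_matrix")
  }
  design <- build_design(phenotypes, standardize = standardize)
  if (is.null(fit)) fit <- fit_polygenic(design$y, design$X, kinship)

  qc <- variant_qc(genotypes, maf_min = maf_min, info_min = info_min)
  out <- purrr::map(models, function(model) {
    scan_one_model(genotypes, fit, model, qc, coded_freq_bounds,
                   recessive_coding)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("gwas_scan", class(res))
  attr(res, "qc_report") <- attr(qc, "report")
  attr(res, "fit") <- fit
  res
}

scan_one_model <- function(genotypes, fit, model, qc, bounds,
                           recessive_coding) {
  m <- nrow(genotypes$variants)
  n <- length(genotypes$samples)
  max_code <- if (model == "additive") 2 else 1
  C <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    C[, j] <- code_genotype_col(
      genotypes$dosage[, j],
      if (is.null(genotypes$gp)) NULL else genotypes$gp[, j, ],
      model, recessive_coding, genotypes$variants$snp[j])
  }
  coded_freq <- colMeans(C) / max_code
  keep <- qc$pass & coded_category_filter(coded_freq, bounds[1], bounds[2])
  res <- tibble::tibble(
    snp = genotypes$variants$snp, chrom = genotypes$variants$chrom,
    pos = genotypes$variants$pos, a0 = genotypes$variants$a0,
    a1 = genotypes$variants$a1, model = model,
    beta = NA_real_, se = NA_real_, p = NA_real_,
    n = as.integer(n), coded_freq = coded_freq, info = genotypes$info
  )
  if (any(keep)) {
    st <- score_test_matrix(C[, keep, drop = FALSE], fit)
    res$beta[keep] <- st$beta
    res$se[keep] <- st$se
    res$p[keep] <- st$p
  }
  res[keep, , drop = FALSE]
}
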