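#' Code a genotype under a genetic model
#'
#' The coded/effect allele is always `a1`. Additive coding is the dosage
#' itself (expected `a1` count in \[0, 2\]). For imputed data the
#' recessive code is the posterior probability of the coded homozygote,
#' `P(hom-a1)`, and the dominant code `P(het) + P(hom-a1)` — the same
#' expectation principle by which dosage generalises hard-call additive
#' coding. With hard calls these reduce to the indicator of
#' `dosage == 2` and `dosage >= 1`. `recessive_coding = "hardcall"`
#' instead thresholds to the best-guess genotype before coding
#' (non-additive models only).
#'
#' @param genotypes A `genotype_matrix`.
#' @param variant_id Variant to code.
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @param recessive_coding `"gp"` (expected code from genotype
#'   probabilities; default) or `"hardcall"` (threshold to best guess).
#' @return List with `model`, `values` (named per-sample codes) and
#'   `coded_freq` (mean code / maximum attainable code: 2 for additive,
#'   1 otherwise) — the frequency of the coded category.
#' @export
code_genotype <- function(genotypes, variant_id,
                          model = c("additive", "dominant", "recessive"),
                          recessive_coding = c("gp", "hardcall")) {
  model <- match.arg(model)
  recessive_coding <- match.arg(recessive_coding)
  j <- match(variant_id, genotypes$variants$snp)
  if (is.na(j)) stop("unknown variant: ", variant_id, call. = FALSE)
  values <- code_genotype_col(genotypes$dosage[, j],
                              if (is.null(genotypes$gp)) NULL else genotypes$gp[, j, ],
                              model, recessive_coding, variant_id)
  names(values) <- genotypes$samples
  max_code <- if (model == "additive") 2 else 1
  list(model = model, values = values, coded_freq = mean(values) / max_code)
}

code_genotype_col <- function(dos, gp, model, recessive_coding, id) {
  if (model == "additive") return(dos)
  hard <- all(abs(dos - round(dos)) < 1e-6)
  if (is.null(gp) && !hard) {
    stop("fractional dosages without genotype probabilities: cannot code ",
         id, " under the ", model,
         " model; supply GP or hard calls", call. = FALSE)
  }
  if (recessive_coding == "hardcall" || is.null(gp)) {
    g <- if (is.null(gp)) round(dos) else max.col(gp) - 1
    if (model == "recessive") as.numeric(g == 2) else as.numeric(g >= 1)
  } else {
    if (model == "recessive") gp[, 3] else gp[, 2] + gp[, 3]
  }
}

#' Post-imputation variant quality control
#'
#' Fails variants whose empirical minor-allele frequency is below
#' `maf_min` (default 0.01) or whose imputation quality is below
#' `info_min` — strict inequalities, so a variant exactly at a threshold
#' passes. Which quality cut applies (INFO < 0.4 for IMPUTE-style
#' pipelines, R-squared < 0.3 for MaCH/minimac-style) is a per-cohort
#' choice made through `info_min`; the stored `info` field is interpreted
#' as whichever metric the cohort's pipeline produced.
#'
#' @param genotypes A `genotype_matrix` with `info` populated (variants
#'   with `NA` info are not tested on that rule).
#' @param maf_min Minimum minor-allele frequency.
#' @param info_min Minimum imputation quality.
#' @return Tibble `snp, maf, info, fail_maf, fail_info, pass`, with a
#'   `"report"` attribute of per-rule failure counts.
#' @export
variant_qc <- function(genotypes, maf_min = 0.01, info_min = 0.4) {
  p <- coded_allele_freq(genotypes)
  maf <- pmin(p, 1 - p)
  fail_maf <- maf < maf_min
  fail_info <- !is.na(genotypes$info) & genotypes$info < info_min
  out <- tibble::tibble(snp = genotypes$variants$snp, maf = maf,
                        info = genotypes$info,
                        fail_maf = fail_maf, fail_info = fail_info,
                        pass = !(fail_maf | fail_info))
  attr(out, "report") <- tibble::tibble(
    rule = c(sprintf("MAF < %g", maf_min), sprintf("info < %g", info_min)),
    n_failed = c(sum(fail_maf), sum(fail_info))
  )
  out
}

#' Coded-category frequency filter
#'
#' Association tests on a nearly empty (or nearly full) coded category
#' are unstable and prone to false positives; variants whose
#' coded-category frequency falls strictly below `low` or strictly above
#' `high` are excluded.
#'
#' @param coded_freq Coded-category frequency (see [code_genotype()]);
#'   vectorised.
#' @param low,high Exclusion bounds (defaults 0.01 and 0.99; a frequency
#'   exactly at a bound passes).
#' @return Logical: `TRUE` when the variant passes.
#' @export
coded_category_filter <- function(coded_freq, low = 0.01, high = 0.99) {
  !(coded_freq < low | coded_freq > high)
}
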