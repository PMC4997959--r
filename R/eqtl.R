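#' Signed -log10(p) association score
#'
#' Encodes both strength and direction of an association in one number:
#' `-log10(p)` when the effect of the coded allele is positive and
#' `+log10(p)` (its negation) when negative, so that concordant
#' association patterns have rank-correlated scores and anti-concordant
#' patterns anti-correlated ones. A zero effect, or `p = 1`, scores 0.
#'
#' @param beta Effect estimate(s) (GWAS beta or eQTL slope).
#' @param p P-value(s) in (0, 1].
#' @return Numeric score(s), `sign(beta) * (-log10(p))`.
#' @export
signed_score <- function(beta, p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    stop("p must lie in (0, 1]", call. = FALSE)
  }
  sign(beta) * (-log10(p))
}

#' Restrict association records to a locus window
#'
#' @param results Tibble with `chrom` and `pos` (1-based).
#' @param chrom Chromosome.
#' @param start,stop Inclusive bounds in base pairs. Defaults are the
#'   recombination-hotspot-delimited PDSS2 coffee-consumption signal,
#'   chr6:107,400,000-107,900,000.
#' @return The rows inside the window, input order preserved.
#' @export
extract_window <- function(results, chrom = "6", start = 107400000,
                           stop = 107900000) {
  stopifnot(start <= stop)
  results[results$chrom == as.character(chrom) &
            results$pos >= start & results$pos <= stop, , drop = FALSE]
}

PALINDROMIC <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonise effect alleles between two sets of association records
#'
#' Matches records on (chrom, pos, unordered allele set). When the second
#' set's effect allele (`a1`) equals the first set's other allele, the
#' second effect (`beta` or `slope`) is sign-flipped so both effects
#' refer to the same allele. Strand-ambiguous pairs (A/T, C/G) cannot be
#' oriented from allele labels alone and are excluded by default;
#' incompatible allele sets are dropped. The counts of both are recorded
#' in the `"harmonization"` attribute.
#'
#' @param a,b Tibbles with `snp, chrom, pos, a0, a1` and an effect column
#'   (`beta` in `a`, `slope` or `beta` in `b`).
#' @param assume_same_strand Keep palindromic variants (appropriate when
#'   both sources are aligned to the same reference strand).
#' @return Tibble of matched pairs: `a`'s columns plus `b`'s effect and p
#'   as `effect_b`, `p_b`.
#' @export
harmonize_alleles <- function(a, b, assume_same_strand = FALSE) {
  eff_b <- if ("slope" %in% names(b)) "slope" else "beta"
  b2 <- tibble::tibble(chrom = as.character(b$chrom), pos = b$pos,
                       b_a0 = b$a0, b_a1 = b$a1,
                       effect_b = b[[eff_b]], p_b = b$p)
  a2 <- dplyr::mutate(a, chrom = as.character(.data$chrom))
  merged <- dplyr::inner_join(a2, b2, by = c("chrom", "pos"),
                              relationship = "many-to-many")
  same <- merged$b_a1 == merged$a1 & merged$b_a0 == merged$a0
  swapped <- merged$b_a1 == merged$a0 & merged$b_a0 == merged$a1
  palin <- paste0(merged$a0, "/", merged$a1) %in% PALINDROMIC
  merged$effect_b[swapped] <- -merged$effect_b[swapped]
  keep <- (same | swapped) & (assume_same_strand | !palin)
  out <- merged[keep, setdiff(names(merged), c("b_a0", "b_a1")), drop = FALSE]
  attr(out, "harmonization") <- tibble::tibble(
    n_matched = sum(keep),
    n_flipped = sum(swapped & keep),
    n_palindromic_excluded = sum((same | swapped) & palin & !assume_same_strand),
    n_incompatible = sum(!(same | swapped))
  )
  out
}

#' Kendall rank correlation of two signed-score vectors
#'
#' Tie-corrected Kendall tau-b with its significance test
#' (exact enumeration for small untied samples, normal approximation
#' otherwise, as implemented by [stats::cor.test()]).
#'
#' @param s_a,s_b Numeric score vectors of equal length (matched pairs).
#' @return One-row tibble `tau, p, n_pairs`.
#' @export
kendall_compare <- function(s_a, s_b) {
  if (length(s_a) != length(s_b)) stop("score vectors differ in length",
                                       call. = FALSE)
  if (length(s_a) < 3) stop("need at least 3 matched pairs", call. = FALSE)
  tau <- stats::cor(s_a, s_b, method = "kendall")
  ct <- suppressWarnings(stats::cor.test(s_a, s_b, method = "kendall"))
  tibble::tibble(tau = tau, p = ct$p.value, n_pairs = length(s_a))
}

#' Compare a GWAS locus pattern against per-tissue cis-eQTL patterns
#'
#' For each tissue: restrict the eQTL records to the locus window,
#' harmonise effect alleles with the GWAS records, build signed
#' `-log10(p)` scores on both sides, and measure their Kendall
#' correlation. A negative tau means alleles that increase the trait
#' decrease expression.
#'
#' @param gwas Association tibble (`snp, chrom, pos, a0, a1, beta, p`).
#' @param eqtl eQTL tibble (`snp, chrom, pos, a0, a1, gene, tissue,
#'   slope, p`); one result row is produced per tissue.
#' @param chrom,start,stop Locus window (see [extract_window()]).
#' @param assume_same_strand Passed to [harmonize_alleles()].
#' @return Tibble `tissue, tau, p, n_pairs`; tissues whose comparison
#'   fails (e.g. too few matched pairs) are reported with `NA` values.
#' @export
compare_all_tissues <- function(gwas, eqtl, chrom = "6",
                                start = 107400000, stop = 107900000,
                                assume_same_strand = FALSE) {
  gwas_w <- extract_window(gwas, chrom, start, stop)
  out <- purrr::map(split(eqtl, eqtl$tissue), function(tis) {
    res <- tryCatch({
      tis_w <- extract_window(tis, chrom, start, stop)
      matched <- harmonize_alleles(gwas_w, tis_w,
                                   assume_same_strand = assume_same_strand)
      kendall_compare(signed_score(matched$beta, matched$p),
                      signed_score(matched$effect_b, matched$p_b))
    }, error = function(e) {
      warning("tissue skipped: ", conditionMessage(e), call. = FALSE)
      tibble::tibble(tau = NA_real_, p = NA_real_, n_pairs = NA_integer_)
    })
    res
  })
  dplyr::bind_rows(out, .id = "tissue")
}
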