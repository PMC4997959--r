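#' Association / meta result schema
#'
#' Internally every association result is a tibble with lower-case columns
#' `snp, chrom, pos, a0, a1, model, beta, se, p, n, coded_freq, info`
#' (single-cohort results) plus optional `cohort`. The on-disk TSV dialect
#' uses the upper-case column names `SNP CHR POS A0 A1 MODEL BETA SE P N
#' CODED_FREQ INFO` (+ `COHORT`).
#'
#' @name sumstats
NULL

sumstat_cols <- c(snp = "SNP", chrom = "CHR", pos = "POS", a0 = "A0", a1 = "A1",
                  model = "MODEL", beta = "BETA", se = "SE", p = "P", n = "N",
                  coded_freq = "CODED_FREQ", info = "INFO", cohort = "COHORT")

validate_sumstats <- function(results, tol = 1e-6) {
  needed <- c("snp", "model", "beta", "se", "p")
  missing_cols <- setdiff(needed, names(results))
  if (length(missing_cols) > 0) {
    stop("summary statistics missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(results$se <= 0, na.rm = TRUE)) stop("se must be > 0", call. = FALSE)
  if (any(results$p <= 0 | results$p > 1, na.rm = TRUE)) {
    stop("p must lie in (0, 1]", call. = FALSE)
  }
  ok <- is.finite(results$beta) & is.finite(results$se) & is.finite(results$p)
  pz <- 2 * stats::pnorm(-abs(results$beta[ok] / results$se[ok]))
  rel <- abs(results$p[ok] - pz) / pmax(pz, .Machine$double.xmin)
  if (any(rel > tol & abs(results$p[ok] - pz) > tol)) {
    stop("p inconsistent with two-sided normal test of beta/se", call. = FALSE)
  }
  invisible(results)
}

#' Write association or meta-analysis summary statistics as TSV
#'
#' @param results Tibble of association results (see [sumstats]). Extra
#'   columns beyond the dialect are preserved under their own names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    stop("no results to write", call. = FALSE)
  }
  validate_sumstats(results)
  known <- sumstat_cols[names(sumstat_cols) %in% names(results)]
  out <- results[, c(names(known), setdiff(names(results), names(known)))]
  names(out)[seq_along(known)] <- unname(known)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read summary statistics TSV
#'
#' @param path File path (dialect of [write_summary_stats()]).
#' @return Tibble with lower-case schema columns.
#' @export
read_summary_stats <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  hit <- match(names(tab), unname(sumstat_cols))
  names(tab)[!is.na(hit)] <- names(sumstat_cols)[hit[!is.na(hit)]]
  for (col in intersect(c("snp", "chrom", "a0", "a1", "model", "cohort"),
                        names(tab))) {
    tab[[col]] <- as.character(tab[[col]])
  }
  if ("pos" %in% names(tab)) tab$pos <- as.integer(tab$pos)
  if ("n" %in% names(tab)) tab$n <- as.integer(tab$n)
  validate_sumstats(tab)
  tab
}

#' Bundled PDSS2 locus summary statistics
#'
#' Published discovery and replication summary statistics for 28 SNPs at
#' the PDSS2 locus on chromosome 6 from a recessive-model genome-wide
#' scan of daily coffee-cup counts: discovery columns (`beta`, `se`, `p`;
#' inverse-variance meta-analysis of two Italian family cohorts) and
#' replication columns (`beta_rep`, `se_rep`, `p_rep`; an independent
#' Dutch family cohort). Effects are on the `log10(cups + 1)` scale per
#' recessive code (coded-allele homozygote vs other genotypes). Positions
#' were printed in Mb and are stored here at that (0.1 Mb) resolution,
#' converted to base pairs.
#'
#' @return Tibble with columns `snp, chrom, pos, a0, a1, beta, se, p,
#'   beta_rep, se_rep, p_rep`.
#' @export
pdss2_locus_summary <- function() {
  path <- system.file("extdata", "pdss2_locus_recessive.tsv", package = "namgwas")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           snp = readr::col_character(),
                           chrom = readr::col_character(),
                           a0 = readr::col_character(),
                           a1 = readr::col_character(),
                           .default = readr::col_double()
                         ))
  tab$pos <- as.integer(tab$pos)
  tab
}
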