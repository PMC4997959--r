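#' Estimate the genomic kinship matrix
#'
#' Classical allele-frequency-weighted genomic kinship from dosages:
#' `K_ij = mean_m (g_im - 2 p_m)(g_jm - 2 p_m) / (4 p_m (1 - p_m))`,
#' averaged over polymorphic variants. The diagonal of this estimator is
#' `0.5 (1 + f_i)` with `f_i` the excess-homozygosity inbreeding
#' estimate, the conventional self-kinship; `2 K` (the covariance scale
#' used by the polygenic model) is positive semi-definite by
#' construction. Monomorphic variants are skipped.
#'
#' @param genotypes A `genotype_matrix` (typically the genotyped backbone
#'   SNPs, not the full imputed set).
#' @return A `kinship_matrix`: list with `samples` and the n x n matrix `K`.
#' @export
estimate_kinship <- function(genotypes) {
  G <- genotypes$dosage
  if (nrow(G) < 2) stop("need at least 2 samples", call. = FALSE)
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all variants monomorphic; cannot estimate kinship",
                       call. = FALSE)
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(G, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(4 * p * (1 - p)), `/`)
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(genotypes$samples, genotypes$samples)
  structure(list(samples = genotypes$samples, K = K,
                 n_variants = ncol(Z)),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  off <- x$K[upper.tri(x$K)]
  cat(sprintf("<kinship_matrix> %d samples, %d variants; mean off-diagonal %.4f, mean diagonal %.4f\n",
              length(x$samples), x$n_variants, mean(off), mean(diag(x$K))))
  invisible(x)
}

#' Read / write a kinship matrix as TSV
#'
#' Dialect: sample ids as header row and first column, kinship
#' coefficients as the body.
#'
#' @param kinship A `kinship_matrix`.
#' @param path File path.
#' @return `path` invisibly (write), or a `kinship_matrix` (read).
#' @export
write_kinship <- function(kinship, path) {
  tab <- tibble::as_tibble(kinship$K, .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(sample = kinship$samples), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           sample = readr::col_character(),
                           .default = readr::col_double()
                         ))
  samples <- tab$sample
  K <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(K) <- list(samples, samples)
  if (max(abs(K - t(K))) > 1e-10) stop("kinship matrix not symmetric", call. = FALSE)
  structure(list(samples = samples, K = K, n_variants = NA_integer_),
            class = "kinship_matrix")
}
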