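#' Genotype matrix container
#'
#' Bundles per-variant dosages (expected counts of the coded allele `a1`,
#' in \[0, 2\]) with optional imputation genotype probabilities and
#' per-variant imputation quality for a set of samples.
#'
#' @param variants Tibble with columns `snp`, `chrom`, `pos`, `a0`, `a1`.
#'   `a1` is always the coded/effect allele; `a0` the other allele.
#' @param samples Character vector of sample ids, one per dosage row.
#' @param dosage Numeric matrix, samples x variants, values in \[0, 2\].
#' @param gp Optional numeric array, samples x variants x 3, giving
#'   P(hom-`a0`), P(het), P(hom-`a1`). Each triplet must sum to 1 and be
#'   consistent with `dosage` (`dosage = gp_het + 2 * gp_hom1`).
#' @param info Optional numeric vector of per-variant imputation quality
#'   in \[0, 1\] (INFO or R-squared, depending on the cohort's pipeline);
#'   `NA` when unknown.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, samples, dosage, gp = NULL, info = NULL) {
  variants <- tibble::as_tibble(variants)
  needed <- c("snp", "chrom", "pos", "a0", "a1")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols) > 0) {
    stop("variants is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dosage <- as.matrix(dosage)
  if (is.null(info)) info <- rep(NA_real_, nrow(variants))
  x <- structure(
    list(variants = variants, samples = as.character(samples),
         dosage = dosage, gp = gp, info = as.numeric(info)),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (gp: %s)\n",
              length(x$samples), nrow(x$variants),
              if (is.null(x$gp)) "absent" else "present"))
  print(utils::head(x$variants, 5))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$variants))

#' Validate a genotype matrix
#'
#' Checks every container invariant: variant metadata well-formed, dosages
#' in \[0, 2\], genotype-probability triplets non-negative, summing to one,
#' and consistent with the dosages. Violations raise errors; nothing is
#' silently repaired.
#'
#' @param x A `genotype_matrix`.
#' @param tol Consistency tolerance for GP sums and GP-implied dosages.
#' @return `x`, invisibly usable, after passing all checks.
#' @export
validate_genotype_matrix <- function(x, tol = 1e-6) {
  v <- x$variants
  if (any(!nzchar(v$snp)) || anyNA(v$snp)) {
    stop("variant ids must be non-empty", call. = FALSE)
  }
  if (any(v$pos < 1, na.rm = TRUE)) stop("positions must be >= 1 (1-based)", call. = FALSE)
  same <- !is.na(v$a0) & !is.na(v$a1) & v$a0 == v$a1
  if (any(same)) {
    stop("allele0 and allele1 identical for: ",
         paste(utils::head(v$snp[same], 3), collapse = ", "), call. = FALSE)
  }
  if (nrow(x$dosage) != length(x$samples) || ncol(x$dosage) != nrow(v)) {
    stop("dosage dimensions do not match samples x variants", call. = FALSE)
  }
  if (anyNA(x$dosage)) {
    stop("missing dosages are not supported; drop incomplete samples upstream",
         call. = FALSE)
  }
  if (any(x$dosage < -tol | x$dosage > 2 + tol)) {
    stop("dosages outside [0, 2]", call. = FALSE)
  }
  if (length(x$info) != nrow(v)) stop("info length != number of variants", call. = FALSE)
  if (any(x$info < 0 | x$info > 1 + tol, na.rm = TRUE)) {
    stop("info scores outside [0, 1]", call. = FALSE)
  }
  if (!is.null(x$gp)) {
    if (!is.array(x$gp) || length(dim(x$gp)) != 3 ||
        !all(dim(x$gp) == c(length(x$samples), nrow(v), 3))) {
      stop("gp must be a samples x variants x 3 array", call. = FALSE)
    }
    if (any(x$gp < -tol)) stop("gp probabilities must be >= 0", call. = FALSE)
    sums <- x$gp[, , 1] + x$gp[, , 2] + x$gp[, , 3]
    if (any(abs(sums - 1) > tol)) {
      stop("gp triplets must sum to 1 (max deviation ",
           format(max(abs(sums - 1))), ")", call. = FALSE)
    }
    implied <- x$gp[, , 2] + 2 * x$gp[, , 3]
    if (any(abs(implied - x$dosage) > tol)) {
      stop("dosage inconsistent with gp (dosage must equal gp_het + 2*gp_hom1)",
           call. = FALSE)
    }
  }
  x
}

#' Coded-allele frequencies from dosages
#'
#' @param genotypes A `genotype_matrix`.
#' @return Numeric vector of per-variant `a1` frequencies (mean dosage / 2).
#' @export
coded_allele_freq <- function(genotypes) {
  colMeans(genotypes$dosage) / 2
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF input must carry `DS` (dosage) and/or `GP` (three genotype
#' probabilities ordered hom-ref, het, hom-alt) FORMAT fields; when only
#' `GP` is present the dosage is derived as `gp_het + 2 * gp_hom1`, and
#' when both are present they must agree. The TSV dialect is
#' `sample <variant_id> ...` with one row per sample and decimal dosages;
#' it carries no allele or position metadata, which is filled with `NA`.
#'
#' @param path File path.
#' @param format `"vcf"` or `"tsv"`; guessed from the extension by default.
#' @return A `genotype_matrix` with variants in file order.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  variants <- tibble::tibble(
    snp = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                 paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    a0 = fix[, "REF"],
    a1 = fix[, "ALT"]
  )
  multi <- grepl(",", variants$a1)
  if (any(multi)) {
    stop("multi-allelic records not supported: ",
         paste(utils::head(variants$snp[multi], 3), collapse = ", "), call. = FALSE)
  }
  fmt <- vcf@gt[, 1]
  has_ds <- any(grepl("(^|:)DS(:|$)", fmt))
  has_gp <- any(grepl("(^|:)GP(:|$)", fmt))
  if (!has_ds && !has_gp) {
    stop("VCF carries neither DS nor GP FORMAT fields", call. = FALSE)
  }
  gp <- NULL
  if (has_gp) {
    gp_chr <- vcfR::extract.gt(vcf, element = "GP")  # variants x samples
    gp <- parse_gp_strings(gp_chr, variants$snp)
  }
  samples <- colnames(vcf@gt)[-1]
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    if (anyNA(ds)) {
      bad <- which(apply(is.na(ds), 1, any))[1]
      stop("unparseable or missing DS at record ", variants$snp[bad], call. = FALSE)
    }
    dosage <- t(ds)
  } else {
    dosage <- matrix(gp[, , 2] + 2 * gp[, , 3], nrow = dim(gp)[1])
  }
  rownames(dosage) <- samples
  genotype_matrix(variants, samples = samples, dosage = dosage, gp = gp)
}

# gp_chr: variants x samples character matrix of "p0,p1,p2"
parse_gp_strings <- function(gp_chr, snp_ids) {
  n_var <- nrow(gp_chr); n_samp <- ncol(gp_chr)
  gp <- array(NA_real_, dim = c(n_samp, n_var, 3))
  for (j in seq_len(n_var)) {
    parts <- strsplit(gp_chr[j, ], ",", fixed = TRUE)
    len3 <- lengths(parts) == 3
    if (any(!len3) || anyNA(gp_chr[j, ])) {
      stop("malformed GP field at record ", snp_ids[j], call. = FALSE)
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 3, byrow = TRUE)
    if (anyNA(m)) stop("malformed GP field at record ", snp_ids[j], call. = FALSE)
    gp[, j, ] <- m
  }
  gp
}

read_genotypes_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           sample = readr::col_character(),
                           .default = readr::col_double()
                         ))
  if (names(tab)[1] != "sample") {
    stop("genotype TSV must start with a 'sample' column (line 1)", call. = FALSE)
  }
  ids <- names(tab)[-1]
  dosage <- as.matrix(tab[, -1, drop = FALSE])
  rownames(dosage) <- tab$sample
  variants <- tibble::tibble(snp = ids, chrom = NA_character_, pos = NA_integer_,
                             a0 = NA_character_, a1 = NA_character_)
  genotype_matrix(variants, samples = tab$sample, dosage = dosage)
}

#' Write genotype dosages as TSV
#'
#' Writes the plain dosage dialect (`sample` column then one column per
#' variant id). Allele metadata and genotype probabilities are not part
#' of this dialect and are dropped.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  validate_genotype_matrix(genotypes)
  tab <- tibble::as_tibble(genotypes$dosage, .name_repair = "minimal")
  names(tab) <- genotypes$variants$snp
  tab <- dplyr::bind_cols(tibble::tibble(sample = genotypes$samples), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Subset a genotype matrix
#'
#' @param genotypes A `genotype_matrix`.
#' @param samples Optional character vector of sample ids to keep (in the
#'   given order).
#' @param snps Optional character vector of variant ids to keep.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(genotypes, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_along(genotypes$samples) else {
    idx <- match(samples, genotypes$samples)
    if (anyNA(idx)) stop("unknown sample(s): ",
                         paste(utils::head(samples[is.na(idx)], 3), collapse = ", "),
                         call. = FALSE)
    idx
  }
  vi <- if (is.null(snps)) seq_len(nrow(genotypes$variants)) else {
    idx <- match(snps, genotypes$variants$snp)
    if (anyNA(idx)) stop("unknown variant(s): ",
                         paste(utils::head(snps[is.na(idx)], 3), collapse = ", "),
                         call. = FALSE)
    idx
  }
  genotype_matrix(
    variants = genotypes$variants[vi, , drop = FALSE],
    samples = genotypes$samples[si],
    dosage = genotypes$dosage[si, vi, drop = FALSE],
    gp = if (is.null(genotypes$gp)) NULL else genotypes$gp[si, vi, , drop = FALSE],
    info = genotypes$info[vi]
  )
}
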