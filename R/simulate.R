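#' Simulation configuration
#'
#' Conditions for the synthetic family cohorts used throughout the test
#' suite: nuclear families (two founders plus a sibship), hard-call
#' genotypes by Hardy-Weinberg founders and Mendelian gene-dropping,
#' optional degradation to imputation-like dosages, and a cup-count
#' phenotype carrying causal, polygenic, covariate and residual variance
#' on the latent `log10(cups + 1)` scale.
#'
#' Defaults mirror an Italian-style discovery cohort: mean consumption
#' near two cups per day (`intercept = 0.45` on the log10 scale),
#' residual sd `sigma_e = 0.18`, narrow-sense polygenic heritability 0.3
#' (twin estimates for coffee consumption run 0.36-0.58; part of that is
#' captured by the causal variant in non-null simulations), and mild sex
#' and age covariate effects.
#'
#' @param n_families Number of nuclear families.
#' @param mean_sibs Mean sibship size (sibs ~ 1 + Poisson(mean_sibs - 1)).
#' @param n_variants Number of independent variants to simulate.
#' @param maf_range Uniform bounds for per-variant founder MAF.
#' @param target_info Imputation quality to degrade hard calls to; 1
#'   leaves hard calls untouched.
#' @param h2_polygenic Polygenic heritability of the latent trait,
#'   relative to polygenic + residual variance.
#' @param sigma_e Residual sd on the latent (log10 cups) scale.
#' @param intercept Latent-scale intercept.
#' @param sex_effect,age_effect Fixed covariate effects (age effect per
#'   year, age centred at 50 before applying it).
#' @param med_fraction Fraction on hypertensive medication, independent
#'   of genotype.
#' @param seed Integer seed; every generator is reproducible given
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_families = 100, mean_sibs = 3, n_variants = 200,
                       maf_range = c(0.05, 0.5), target_info = 1,
                       h2_polygenic = 0.3, sigma_e = 0.18, intercept = 0.45,
                       sex_effect = 0.05, age_effect = 0.002,
                       med_fraction = 0.05, seed = 1L) {
  stopifnot(n_families >= 1, mean_sibs >= 1, n_variants >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            target_info > 0, target_info <= 1,
            h2_polygenic >= 0, h2_polygenic < 1, sigma_e > 0,
            med_fraction >= 0, med_fraction < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Causal-variant specification
#'
#' @param variant_id Id of the causal variant in the genotype matrix.
#' @param model Genetic model of the effect.
#' @param beta Effect on the latent `log10(cups + 1)` scale per unit of
#'   the model code.
#' @param freq Frequency of the coded (effect) allele in founders, in
#'   (0, 1); it need not be the minor allele — a recessive effect with a
#'   common coded-homozygote class requires a common coded allele.
#' @return A `causal_spec` list.
#' @export
causal_spec <- function(variant_id, model = c("recessive", "additive", "dominant"),
                        beta, freq) {
  model <- match.arg(model)
  stopifnot(is.finite(beta), freq > 0, freq < 1)
  structure(list(variant_id = variant_id, model = model,
                 beta = beta, freq = freq), class = "causal_spec")
}

#' Simulate nuclear-family pedigrees
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `id`, `father`, `mother` (`NA` for
#'   founders), `sex` (0/1), `family`; parents precede children.
#' @export
simulate_pedigree <- function(config) {
  set.seed(config$seed)
  rows <- purrr::map(seq_len(config$n_families), function(f) {
    n_sibs <- 1L + stats::rpois(1, config$mean_sibs - 1)
    fa <- sprintf("F%04d_p1", f); mo <- sprintf("F%04d_p2", f)
    kids <- sprintf("F%04d_o%d", f, seq_len(n_sibs))
    tibble::tibble(
      id = c(fa, mo, kids),
      father = c(NA, NA, rep(fa, n_sibs)),
      mother = c(NA, NA, rep(mo, n_sibs)),
      sex = c(1L, 0L, stats::rbinom(n_sibs, 1, 0.5)),
      family = f
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate hard-call genotypes by gene-dropping
#'
#' Founders are drawn from Hardy-Weinberg equilibrium at per-variant
#' allele frequencies; each offspring genotype is the sum of one allele
#' transmitted from each parent (probability = parental allele count / 2,
#' independently per variant — family co-inheritance only, no LD).
#'
#' @param pedigree Output of [simulate_pedigree()].
#' @param config A [sim_config()].
#' @param causal Optional list of [causal_spec()]s; their variants are
#'   appended after the `n_variants` background variants, at the
#'   specified coded-allele frequency.
#' @return A `genotype_matrix` of hard calls (dosages in {0,1,2},
#'   degenerate gp, info = 1).
#' @export
simulate_genotypes <- function(pedigree, config, causal = list()) {
  if (inherits(causal, "causal_spec")) causal <- list(causal)
  set.seed(config$seed + 1L)
  m_bg <- config$n_variants
  freqs <- c(stats::runif(m_bg, config$maf_range[1], config$maf_range[2]),
             vapply(causal, `[[`, numeric(1), "freq"))
  ids <- c(sprintf("snp%05d", seq_len(m_bg)),
           vapply(causal, `[[`, character(1), "variant_id"))
  if (anyDuplicated(ids)) stop("duplicate variant ids", call. = FALSE)
  m <- length(freqs)
  n <- nrow(pedigree)
  G <- matrix(0L, n, m, dimnames = list(pedigree$id, ids))
  founder <- is.na(pedigree$father)
  G[founder, ] <- stats::rbinom(sum(founder) * m, 2,
                                rep(freqs, each = sum(founder)))
  fi <- match(pedigree$father, pedigree$id)
  mi <- match(pedigree$mother, pedigree$id)
  kids <- which(!founder)
  for (k in kids) {
    G[k, ] <- stats::rbinom(m, 1, G[fi[k], ] / 2) +
      stats::rbinom(m, 1, G[mi[k], ] / 2)
  }
  variants <- tibble::tibble(
    snp = ids, chrom = "1",
    pos = as.integer(seq_len(m) * 10000L),
    a0 = "A", a1 = "G"
  )
  gp <- array(0, dim = c(n, m, 3))
  for (g in 0:2) gp[, , g + 1][G == g] <- 1
  genotype_matrix(variants, pedigree$id, dosage = G * 1.0, gp = gp,
                  info = rep(1, m))
}

#' Degrade hard calls to imputation-like dosages
#'
#' Blends each hard-call genotype-probability triplet with the
#' Hardy-Weinberg background at the variant's empirical allele frequency,
#' `gp' = a * gp + (1 - a) * hwe`, choosing the blend weight so the
#' realised INFO — `var(dosage) / (2 p (1 - p))` with `p` the empirical
#' coded-allele frequency — matches `target_info`. Since the blended
#' dosage is `a * g + (1 - a) * 2p`, realised INFO scales as `a^2` times
#' the hard-call INFO and the blend is solved in closed form; the
#' degradation is deterministic given its input.
#'
#' @param genotypes Hard-call `genotype_matrix`.
#' @param target_info Target INFO in (0, 1]; 1 returns the input.
#' @param seed Unused at present (the closed-form blend is
#'   deterministic); kept so callers can treat all generators uniformly.
#' @return A `genotype_matrix` with fractional dosages, blended gp and
#'   realised per-variant info.
#' @export
degrade_to_imputed <- function(genotypes, target_info, seed = 1L) {
  if (target_info <= 0 || target_info > 1) {
    stop("target_info must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(genotypes$gp)) stop("hard-call input with gp required", call. = FALSE)
  if (target_info == 1) return(genotypes)
  G <- genotypes$dosage
  p <- colMeans(G) / 2
  v <- apply(G, 2, stats::var) * (nrow(G) - 1) / nrow(G)
  denom <- 2 * p * (1 - p)
  info_hard <- ifelse(denom > 0, v / denom, 0)
  a <- ifelse(info_hard > 0, pmin(1, sqrt(target_info / info_hard)), 1)
  hwe <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
  gp <- genotypes$gp
  for (k in 1:3) {
    gp[, , k] <- sweep(sweep(genotypes$gp[, , k], 2, a, `*`),
                       2, (1 - a) * hwe[, k], `+`)
  }
  dosage <- gp[, , 2] + 2 * gp[, , 3]
  pd <- colMeans(dosage) / 2
  vd <- apply(dosage, 2, stats::var) * (nrow(dosage) - 1) / nrow(dosage)
  info <- ifelse(pd > 0 & pd < 1, vd / (2 * pd * (1 - pd)), 0)
  genotype_matrix(genotypes$variants, genotypes$samples, dosage,
                  gp = gp, info = pmin(info, 1))
}

model_code_values <- function(dosage_col, gp_slice, model) {
  switch(model,
         additive = dosage_col,
         recessive = gp_slice[, 3],
         dominant = gp_slice[, 2] + gp_slice[, 3])
}

#' Simulate the coffee-cup phenotype
#'
#' Builds the latent trait `intercept + sum(causal effects) + polygenic +
#' sex and age effects + N(0, sigma_e)`, where the polygenic value is
#' propagated through the pedigree (founders `N(0, sigma_g^2)`, offspring
#' = mid-parent + segregation noise `N(0, sigma_g^2 / 2)`) with
#' `sigma_g^2 = h2 / (1 - h2) * sigma_e^2`, and inverts the analysis
#' transform: `cups = max(round(10^latent - 1), 0)`. The rounding is
#' deterministic so the causal beta stays exactly interpretable on the
#' `log10(cups + 1)` analysis scale.
#'
#' @param genotypes `genotype_matrix` containing every causal variant.
#' @param pedigree The pedigree the genotypes were dropped on.
#' @param causal List of [causal_spec()]s (possibly empty).
#' @param config A [sim_config()].
#' @return Phenotype tibble (`sample, cups_per_day, sex, age,
#'   hypertensive_med, y_transformed`) plus a `latent` column and a
#'   `"truth"` attribute recording the generating parameters.
#' @export
simulate_phenotype <- function(genotypes, pedigree, causal = list(), config) {
  if (inherits(causal, "causal_spec")) causal <- list(causal)
  set.seed(config$seed + 2L)
  n <- nrow(pedigree)
  stopifnot(identical(genotypes$samples, pedigree$id))
  sigma_g2 <- if (config$h2_polygenic > 0) {
    config$h2_polygenic / (1 - config$h2_polygenic) * config$sigma_e^2
  } else 0
  a <- numeric(n)
  founder <- is.na(pedigree$father)
  a[founder] <- stats::rnorm(sum(founder), 0, sqrt(sigma_g2))
  fi <- match(pedigree$father, pedigree$id)
  mi <- match(pedigree$mother, pedigree$id)
  kids <- which(!founder)
  a[kids] <- (a[fi[kids]] + a[mi[kids]]) / 2 +
    stats::rnorm(length(kids), 0, sqrt(sigma_g2 / 2))
  g_term <- numeric(n)
  for (cs in causal) {
    j <- match(cs$variant_id, genotypes$variants$snp)
    if (is.na(j)) stop("causal variant not in genotypes: ", cs$variant_id,
                       call. = FALSE)
    code <- model_code_values(genotypes$dosage[, j],
                              genotypes$gp[, j, , drop = TRUE], cs$model)
    g_term <- g_term + cs$beta * code
  }
  age <- stats::runif(n, 18, 80)
  latent <- config$intercept + g_term + a +
    config$sex_effect * pedigree$sex + config$age_effect * (age - 50) +
    stats::rnorm(n, 0, config$sigma_e)
  cups <- pmax(round(10^latent - 1), 0)
  out <- tibble::tibble(
    sample = pedigree$id,
    cups_per_day = as.integer(cups),
    sex = pedigree$sex,
    age = age,
    hypertensive_med = stats::runif(n) < config$med_fraction,
    y_transformed = transform_cups(as.integer(cups)),
    latent = latent
  )
  attr(out, "truth") <- list(causal = causal, h2_polygenic = config$h2_polygenic,
                             sigma_g2 = sigma_g2, sigma_e = config$sigma_e,
                             seed = config$seed)
  out
}

#' Simulate a full cohort
#'
#' Convenience wrapper: pedigree, gene-dropped genotypes (optionally
#' degraded to a target INFO), and phenotype.
#'
#' @inheritParams simulate_phenotype
#' @param config A [sim_config()].
#' @param causal List of [causal_spec()]s.
#' @return List with `pedigree`, `genotypes`, `phenotypes`.
#' @export
simulate_cohort <- function(config, causal = list()) {
  ped <- simulate_pedigree(config)
  geno <- simulate_genotypes(ped, config, causal)
  pheno <- simulate_phenotype(geno, ped, causal, config)
  if (config$target_info < 1) {
    geno <- degrade_to_imputed(geno, config$target_info, seed = config$seed + 3L)
  }
  list(pedigree = ped, genotypes = geno, phenotypes = pheno)
}

#' Simulate a cis-eQTL association pattern against a GWAS pattern
#'
#' For a `shared_fraction` of the variants the eQTL signed score is a
#' noisy copy of the GWAS signed score with the requested sign
#' relationship (negative: higher consumption-increasing alleles lower
#' expression); the remaining variants are null (p uniform, random slope
#' sign).
#'
#' @param gwas_results Association tibble with `snp, chrom, pos, a0, a1,
#'   beta, p`.
#' @param shared_fraction Fraction of variants sharing the signal, in
#'   \[0, 1\].
#' @param sign_correlation `"negative"` or `"positive"`.
#' @param noise_sd Sd of the noise added to the shared signed scores.
#' @param gene,tissue Labels copied to the output.
#' @param seed Integer seed.
#' @return Tibble of eQTL records: `snp, chrom, pos, a0, a1, gene,
#'   tissue, slope, p`.
#' @export
simulate_eqtl_pattern <- function(gwas_results, shared_fraction = 1,
                                  sign_correlation = c("negative", "positive"),
                                  noise_sd = 0.5, gene = "PDSS2",
                                  tissue = "synthetic", seed = 1L) {
  sign_correlation <- match.arg(sign_correlation)
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(gwas_results) == 0) stop("gwas_results is empty", call. = FALSE)
  set.seed(seed)
  n <- nrow(gwas_results)
  s_gwas <- signed_score(gwas_results$beta, gwas_results$p)
  mult <- if (sign_correlation == "negative") -1 else 1
  n_shared <- round(shared_fraction * n)
  shared <- seq_len(n) <= n_shared
  s <- numeric(n)
  s[shared] <- mult * s_gwas[shared] +
    if (noise_sd > 0) stats::rnorm(n_shared, 0, noise_sd) else 0
  if (any(!shared)) {
    p_null <- stats::runif(sum(!shared))
    s[!shared] <- sample(c(-1, 1), sum(!shared), replace = TRUE) *
      (-log10(p_null))
  }
  tibble::tibble(
    snp = gwas_results$snp, chrom = gwas_results$chrom,
    pos = gwas_results$pos, a0 = gwas_results$a0, a1 = gwas_results$a1,
    gene = gene, tissue = tissue,
    slope = ifelse(s == 0, 0, sign(s)) * (0.1 + 0.05 * abs(s)),
    p = pmin(10^(-abs(s)), 1)
  )
}
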