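test_that("pedigrees are nuclear, ordered and reproducible", {
  cfg <- sim_config(n_families = 30, seed = 5)
  ped <- simulate_pedigree(cfg)
  expect_equal(sum(is.na(ped$father)), 60L)  # two founders per family
  expect_true(all(table(ped$family) >= 3))
  # parents precede children
  fi <- match(ped$father, ped$id)
  expect_true(all(fi[!is.na(fi)] < which(!is.na(ped$father))))
  non_founders <- !is.na(ped$father)
  expect_true(all(!is.na(ped$mother[non_founders])))
  expect_identical(ped, simulate_pedigree(cfg))
})

test_that("founder genotypes follow Hardy-Weinberg at the requested MAF", {
  cfg <- sim_config(n_families = 1000, mean_sibs = 1, n_variants = 1,
                    maf_range = c(0.3, 0.3), seed = 8)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  founders <- geno$dosage[is.na(ped$father), 1]
  freqs <- tabulate(founders + 1, 3) / length(founders)
  # binomial error at n = 2000 founders: ~3 sd
  expect_equal(freqs, c(0.49, 0.42, 0.09), tolerance = 0.045)
})

test_that("gene-dropping never violates Mendelian transmission", {
  cfg <- sim_config(n_families = 80, n_variants = 40, seed = 9)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  fi <- match(ped$father, ped$id); mi <- match(ped$mother, ped$id)
  for (k in which(!is.na(fi))) {
    gf <- geno$dosage[fi[k], ]; gm <- geno$dosage[mi[k], ]
    gc <- geno$dosage[k, ]
    expect_true(all(gc >= (gf == 2) + (gm == 2)))
    expect_true(all(gc <= (gf > 0) + (gm > 0)))
  }
})

test_that("sib pairs show kinship 0.25 in the genome", {
  cfg <- sim_config(n_families = 200, mean_sibs = 2, n_variants = 800, seed = 10)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  k <- estimate_kinship(geno)
  fi <- match(ped$father, ped$id)
  sib_k <- c()
  for (fam in split(seq_len(nrow(ped)), ped$family)) {
    kids <- fam[!is.na(fi[fam])]
    if (length(kids) >= 2) {
      prs <- utils::combn(kids, 2)
      sib_k <- c(sib_k, k$K[t(prs)])
    }
  }
  expect_gt(length(sib_k), 100)
  expect_equal(mean(sib_k), 0.25, tolerance = 3 * sd(sib_k) / sqrt(length(sib_k)) + 0.01)
})

test_that("imputation degradation hits the target INFO and is monotone", {
  cfg <- sim_config(n_families = 500, mean_sibs = 1, n_variants = 30,
                    maf_range = c(0.2, 0.2), seed = 12)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  expect_identical(degrade_to_imputed(geno, 1), geno)  # identity limit
  deg <- degrade_to_imputed(geno, 0.6)
  expect_true(all(deg$info > 0.55 & deg$info < 0.65))
  validate_genotype_matrix(deg)  # gp still coherent with dosages
  realized <- sapply(c(0.2, 0.5, 0.8),
                     function(t) mean(degrade_to_imputed(geno, t)$info))
  expect_true(all(diff(realized) > 0))
  expect_error(degrade_to_imputed(geno, 0), "target_info")
  expect_error(degrade_to_imputed(geno, 1.2), "target_info")
})

test_that("null phenotypes carry no genotype signal", {
  cfg <- sim_config(n_families = 400, h2_polygenic = 0, n_variants = 5, seed = 13)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotype(geno, ped, list(), cfg)
  fit <- summary(lm(ph$y_transformed ~ geno$dosage[, 1]))
  expect_lt(abs(fit$coefficients[2, 3]), 3)
})

test_that("a recessive causal effect shifts coded homozygotes by beta", {
  cfg <- sim_config(n_families = 500, h2_polygenic = 0, sigma_e = 0.05,
                    n_variants = 5, seed = 14)
  cs <- causal_spec("rsX", "recessive", beta = 0.2, freq = 0.55)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg, list(cs))
  ph <- simulate_phenotype(geno, ped, list(cs), cfg)
  hom <- geno$dosage[, "rsX"] == 2
  diff_lat <- mean(ph$latent[hom]) - mean(ph$latent[!hom])
  # age/sex noise enters both groups equally; MC error a few times
  # sigma_latent / sqrt(n)
  expect_equal(diff_lat, 0.2, tolerance = 0.03)
})

test_that("cup counts invert the latent transform deterministically", {
  cfg <- sim_config(n_families = 50, seed = 15)
  co <- simulate_cohort(cfg)
  ph <- co$phenotypes
  expect_equal(ph$cups_per_day, as.integer(pmax(round(10^ph$latent - 1), 0)))
  # latent exactly 1 maps to 9 cups
  expect_equal(pmax(round(10^1 - 1), 0), 9)
  expect_equal(ph$y_transformed, log10(ph$cups_per_day + 1))
})

test_that("generators are bit-reproducible given the seed", {
  cfg <- sim_config(n_families = 20, n_variants = 30, seed = 77)
  cs <- causal_spec("c1", "dominant", beta = 0.05, freq = 0.3)
  a <- simulate_cohort(cfg, list(cs))
  b <- simulate_cohort(cfg, list(cs))
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("latent-scale heritability is recovered at n >= 2000", {
  cfg <- sim_config(n_families = 400, n_variants = 20, h2_polygenic = 0.4,
                    seed = 16)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotype(geno, ped, list(), cfg)
  expect_gte(nrow(ped), 2000)
  k <- pedigree_kinship(ped)
  X <- cbind(intercept = 1, sex = ph$sex, age = ph$age)
  fit <- fit_polygenic(ph$latent, X, k)
  expect_equal(fit$h2, 0.4, tolerance = 0.1)
})

test_that("eQTL pattern generator produces the planted concordance", {
  gwas <- window_gwas(40, seed = 21)
  anti <- simulate_eqtl_pattern(gwas, shared_fraction = 1,
                                sign_correlation = "negative",
                                noise_sd = 0, seed = 3)
  tau <- kendall_compare(signed_score(gwas$beta, gwas$p),
                         signed_score(anti$slope, anti$p))
  expect_equal(tau$tau, -1)  # exact anti-concordance
  null <- simulate_eqtl_pattern(gwas, shared_fraction = 0, noise_sd = 0,
                                seed = 4)
  tau0 <- kendall_compare(signed_score(gwas$beta, gwas$p),
                          signed_score(null$slope, null$p))
  # null sampling bound: sd(tau) ~ sqrt(2(2n+5)/(9n(n-1)))
  expect_lt(abs(tau0$tau), 3 * sqrt(2 * 85 / (9 * 40 * 39)))
  expect_error(simulate_eqtl_pattern(gwas, shared_fraction = 1.5), "shared_fraction")
})
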