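test_that("inverse-variance pooling closed forms", {
  one <- inverse_variance_meta(0.05, 0.01)
  expect_equal(one$beta, 0.05)
  expect_equal(one$se, 0.01)
  two <- inverse_variance_meta(c(0.02, 0.06), c(0.01, 0.01))
  expect_equal(two$beta, 0.04)                  # equal se: plain mean
  expect_equal(two$se, 0.01 / sqrt(2))
  expect_error(inverse_variance_meta(c(0.1), c(0)), "standard errors")
  expect_error(inverse_variance_meta(numeric(0), numeric(0)), "no studies")
})

test_that("the locus worked example pools below its discovery p", {
  # rs2216084: discovery (0.082, 0.014), replication (0.037, 0.014)
  pooled <- inverse_variance_meta(c(0.082, 0.037), c(0.014, 0.014))
  expect_equal(pooled$beta, 0.0595, tolerance = 1e-12)
  expect_equal(pooled$se, 0.014 / sqrt(2), tolerance = 1e-12)
  # frozen from the closed form: 2*pnorm(-0.0595*sqrt(2)/0.014)
  expect_equal(pooled$p, 1.846823e-09, tolerance = 1e-4)
  expect_lt(pooled$p, 9.25e-09)
})

test_that("pooled variance never exceeds the smallest input variance", {
  set.seed(31)
  for (r in 1:25) {
    k <- sample(2:6, 1)
    beta <- rnorm(k, 0, 0.1); se <- runif(k, 0.005, 0.05)
    m <- inverse_variance_meta(beta, se)
    expect_lt(m$se, min(se))
    # concordant equal effects: pooled p <= every input p
    m2 <- inverse_variance_meta(rep(0.05, k), se)
    expect_true(all(m2$p <= 2 * pnorm(-abs(0.05 / se)) + 1e-12))
  }
})

test_that("meta-analysis of cohort tables is model-agnostic and order-invariant", {
  set.seed(32)
  mk <- function(model, shift = 0) {
    beta <- rnorm(10, shift, 0.05); se <- runif(10, 0.01, 0.03)
    tibble::tibble(snp = paste0("rs", 1:10), chrom = "2",
                   pos = as.integer(1:10 * 1000), a0 = "A", a1 = "G",
                   model = model, beta = beta, se = se,
                   p = 2 * pnorm(-abs(beta / se)), n = 400L,
                   coded_freq = runif(10), info = 1)
  }
  c1a <- mk("recessive"); c2a <- mk("recessive", 0.02)
  m_rec <- meta_analyse(ingi_a = c1a, ingi_b = c2a)
  c1b <- dplyr::mutate(c1a, model = "additive")
  c2b <- dplyr::mutate(c2a, model = "additive")
  m_add <- meta_analyse(ingi_a = c1b, ingi_b = c2b)
  expect_equal(m_rec$beta, m_add$beta)          # identical arithmetic per model
  expect_equal(m_rec$p, m_add$p)
  m_swap <- meta_analyse(ingi_b = c2a, ingi_a = c1a)
  expect_equal(m_rec[c("snp", "beta", "se", "p")],
               m_swap[c("snp", "beta", "se", "p")])
  # agreement with the scalar pooling on one variant
  m1 <- inverse_variance_meta(c(c1a$beta[1], c2a$beta[1]),
                              c(c1a$se[1], c2a$se[1]))
  expect_equal(m_rec$beta[m_rec$snp == "rs1"], m1$beta)
})

test_that("variants absent from a cohort are dropped unless told otherwise", {
  t1 <- tibble::tibble(snp = c("rs1", "rs2"), chrom = "1", pos = c(1L, 2L),
                       a0 = "A", a1 = "G", model = "recessive",
                       beta = c(0.1, 0.2), se = 0.05,
                       p = 2 * pnorm(-abs(c(0.1, 0.2) / 0.05)))
  t2 <- t1[1, ]
  expect_equal(nrow(meta_analyse(t1, t2)), 1L)
  expect_equal(nrow(meta_analyse(t1, t2, require_all_cohorts = FALSE)), 2L)
})

test_that("genomic control matches the chi-square median definition", {
  set.seed(33)
  z <- rnorm(50000)
  res <- tibble::tibble(snp = paste0("v", seq_along(z)), beta = z, se = 1,
                        p = 2 * pnorm(-abs(z)))
  gc <- genomic_control(res)
  lambda <- attr(gc, "lambda")
  expect_equal(lambda, median(z^2) / qchisq(0.5, 1), tolerance = 1e-12)
  expect_true(lambda > 0.95 && lambda < 1.05)  # null calibration of the statistic
  # doubling every chi-square doubles lambda and leaves corrected stats equal
  res2 <- dplyr::mutate(res, beta = beta * sqrt(2),
                        p = 2 * pnorm(-abs(beta / se)))
  gc2 <- genomic_control(res2)
  expect_equal(attr(gc2, "lambda"), 2 * lambda, tolerance = 1e-12)
  if (lambda > 1) expect_equal(gc2$p, gc$p, tolerance = 1e-9)
})

test_that("deflation only applies when lambda exceeds one", {
  set.seed(34)
  z <- rnorm(500, 0, 0.5)  # deflated statistics
  res <- tibble::tibble(snp = paste0("v", 1:500), beta = z, se = 1,
                        p = 2 * pnorm(-abs(z)))
  gc <- genomic_control(res)
  expect_lt(attr(gc, "lambda"), 1)
  expect_equal(gc$p, res$p)  # untouched
  expect_equal(unique(gc$lambda_applied), attr(gc, "lambda"))
  expect_error(genomic_control(res[0, ]), "no results")
  expect_warning(genomic_control(res[1:50, ]), "fewer than 100")
})

test_that("the effective-tests threshold arithmetic", {
  th <- significance_threshold(5e-8, 2.2)
  expect_equal(th$threshold, 5e-8 / 2.2)
  expect_equal(signif(th$threshold, 3), 2.27e-8)
  expect_equal(significance_threshold(5e-8, 1)$threshold, 5e-8)
  expect_equal(significance_threshold(0.05, 2.2)$threshold, 0.022727273,
               tolerance = 1e-7)
  expect_error(significance_threshold(0, 2.2), "positive")
})

test_that("replication demands small p AND concordant direction", {
  disc <- tibble::tibble(snp = c("a", "b", "c"), a0 = "A", a1 = "G",
                         beta = c(0.08, 0.08, 0.08), se = 0.014,
                         p = rep(1e-9, 3))
  repl <- tibble::tibble(snp = c("a", "b", "c"), a0 = "A", a1 = "G",
                         beta = c(0.03, 0.03, -0.05), se = 0.014,
                         p = c(0.01, 0.05, 0.001))
  out <- replication_filter(disc, repl)
  expect_equal(out$replicated, c(TRUE, FALSE, FALSE))  # 0.05 boundary fails
  expect_equal(out$direction_concordant, c(TRUE, TRUE, FALSE))
})

test_that("replication harmonises swapped effect alleles", {
  disc <- tibble::tibble(snp = "a", a0 = "A", a1 = "G", beta = 0.08,
                         se = 0.014, p = 1e-9)
  repl <- tibble::tibble(snp = "a", a0 = "G", a1 = "A", beta = -0.03,
                         se = 0.014, p = 0.01)
  out <- replication_filter(disc, repl)
  expect_equal(out$beta_rep, 0.03)  # flipped to discovery's coded allele
  expect_true(out$replicated)
  # unmatched variants are reported, not fatal
  out2 <- replication_filter(dplyr::mutate(disc, snp = "zzz"), repl)
  expect_true(is.na(out2$replicated))
  expect_equal(attr(out2, "unmatched"), "zzz")
})

test_that("exactly five locus-table variants replicate, all concordant", {
  t1 <- pdss2_locus_summary()
  disc <- t1[, c("snp", "chrom", "pos", "a0", "a1", "beta", "se", "p")]
  repl <- dplyr::transmute(t1, snp, a0, a1, beta = beta_rep, se = se_rep,
                           p = p_rep)
  out <- replication_filter(disc, repl)
  expect_equal(sum(out$replicated), 5L)
  hits <- out[out$replicated, ]
  expect_setequal(hits$snp, c("rs2216084", "rs6942255", "rs7745311",
                              "rs7754744", "rs9386630"))
  expect_true(all(hits$beta > 0 & hits$beta_rep > 0))
})

test_that("pooling all cohorts tightens every replicated hit", {
  t1 <- pdss2_locus_summary()
  disc <- t1[, c("snp", "chrom", "pos", "a0", "a1", "beta", "se", "p")]
  repl <- dplyr::transmute(t1, snp, a0, a1, beta = beta_rep, se = se_rep,
                           p = p_rep)
  out <- pool_all_cohorts(replication_filter(disc, repl))
  expect_true(all(out$improves_discovery[out$replicated]))
  expect_true(all(out$se_pooled < pmin(out$se, out$se_rep) + 1e-12))
  # three identical cohorts: se shrinks by sqrt(3)
  m3 <- inverse_variance_meta(rep(0.05, 3), rep(0.012, 3))
  expect_equal(m3$se, 0.012 / sqrt(3))
})

test_that("two-cohort meta beats both cohorts at a shared causal variant", {
  # two discovery-sized cohorts (~370 and ~840) sharing a recessive signal
  cs <- causal_spec("rsC", "recessive", beta = 0.086, freq = sqrt(0.3))
  wins <- 0; reps <- 20
  for (r in seq_len(reps)) {
    run <- purrr::imap(c(carl = 73, fvg = 166), function(nf, nm) {
      cfg <- sim_config(n_families = nf, n_variants = 80,
                        seed = 3000 + r * 1000 + nf)
      co <- simulate_cohort(cfg, list(cs))
      scan <- run_scan(co$genotypes, apply_exclusions(co$phenotypes),
                       models = "recessive")
      scan[scan$snp == "rsC", ]
    })
    m <- meta_analyse(run)
    p_meta <- m$p[m$snp == "rsC"]
    wins <- wins + (p_meta < min(run[[1]]$p, run[[2]]$p))
  }
  # expected win rate >= 0.9; allow two binomial sd of Monte-Carlo error
  expect_gte(wins, ceiling(0.9 * reps - 2 * sqrt(reps * 0.9 * 0.1)))
})
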