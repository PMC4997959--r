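# Shared fixture builders; everything is generated in code.

# Hand-sized genotype matrix with genotype probabilities.
tiny_genotypes <- function() {
  variants <- tibble::tibble(
    snp = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(100L, 200L, 300L),
    a0 = c("A", "C", "T"),
    a1 = c("G", "T", "C")
  )
  gp <- array(0, dim = c(4, 3, 3))
  # rs1: hard calls 0,1,2,2
  gp[, 1, ] <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 1))
  # rs2: imputed
  gp[, 2, ] <- rbind(c(0.1, 0.2, 0.7), c(0.25, 0.5, 0.25),
                     c(0.9, 0.1, 0), c(0, 0, 1))
  # rs3: hard calls 1,1,0,2
  gp[, 3, ] <- rbind(c(0, 1, 0), c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))
  dosage <- gp[, , 2] + 2 * gp[, , 3]
  genotype_matrix(variants, paste0("s", 1:4), dosage, gp = gp,
                  info = c(1, 0.8, 1))
}

# Unrelated Hardy-Weinberg individuals as a genotype matrix.
founder_genotypes <- function(n, mafs, seed = 1) {
  set.seed(seed)
  m <- length(mafs)
  G <- matrix(stats::rbinom(n * m, 2, rep(mafs, each = n)), n, m)
  gp <- array(0, dim = c(n, m, 3))
  for (g in 0:2) gp[, , g + 1][G == g] <- 1
  variants <- tibble::tibble(snp = paste0("v", seq_len(m)), chrom = "1",
                             pos = seq_len(m) * 100L, a0 = "A", a1 = "G")
  genotype_matrix(variants, paste0("i", seq_len(n)), G * 1.0, gp = gp,
                  info = rep(1, m))
}

# Small family cohort for mixed-model tests.
small_cohort <- function(seed = 1, n_families = 40, n_variants = 120,
                         causal = list(), ...) {
  cfg <- sim_config(n_families = n_families, n_variants = n_variants,
                    seed = seed, ...)
  simulate_cohort(cfg, causal)
}

# Synthetic GWAS pattern with unique positions inside the PDSS2 window.
window_gwas <- function(n = 50, seed = 1) {
  set.seed(seed)
  beta <- stats::rnorm(n, 0, 0.05)
  se <- 0.014
  tibble::tibble(
    snp = paste0("rs", seq_len(n)), chrom = "6",
    pos = as.integer(seq(107400000, 107900000, length.out = n)),
    a0 = "A", a1 = "G", beta = beta, se = se,
    p = 2 * stats::pnorm(-abs(beta / se))
  )
}

# Exhaustive-pair Kendall tau-b oracle (independent of stats::cor).
kendall_tau_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}
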