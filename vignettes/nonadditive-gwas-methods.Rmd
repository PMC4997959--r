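---
title: "Methods: non-additive mixed-model GWAS, meta-analysis and eQTL pattern comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-additive mixed-model GWAS, meta-analysis and eQTL pattern comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

namgwas implements a complete non-additive genome-wide association pipeline
for family-structured cohorts, of the kind used to map habitual coffee
consumption to the *PDSS2* locus: phenotype preparation, genomic kinship and
a polygenic mixed model, additive/dominant/recessive genotype coding with the
accompanying variant filters, inverse-variance meta-analysis with genomic
control and an effective-number-of-tests threshold, replication logic, and a
signed-score Kendall comparison of a GWAS locus against cis-eQTL association
patterns. Because the cohorts such analyses run on are private, the package
also contains a family-based simulator that generates every input the
pipeline needs; all statistical properties quoted below are verified on that
simulator by the test suite and the `scripts/acceptance.R` report.

## The phenotype

Daily coffee consumption is recorded as a cup count and is strongly
right-skewed, so the analysis trait is `log10(cups + 1)`
(`transform_cups()`). Samples drinking more than `max_cups` per day are
excluded as outliers — 9 cups for Italian-style consumption, 20 for
Dutch-style cohorts, whose cup sizes and caffeine content differ — and
samples on hypertensive medication are excluded because they are commonly
advised to limit coffee (`apply_exclusions()`). Both cuts are strict
inequalities: a 9-cup drinker stays at `max_cups = 9`. Sex and age are the
fixed covariates (`build_design()`, column order intercept/sex/age). A
z-standardisation switch exists for sensitivity analyses but the default is
the raw transformed trait, whose effect sizes are directly interpretable:
a recessive effect of 0.086 at a mean of about two cups per day corresponds
to roughly one extra cup for coded-allele homozygotes.

## Kinship and the polygenic mixed model

Family structure induces phenotypic correlation that inflates naive
association tests. `estimate_kinship()` computes the allele-frequency
weighted genomic kinship
\[
K_{ij} = \frac{1}{M}\sum_m \frac{(g_{im} - 2p_m)(g_{jm} - 2p_m)}{4p_m(1-p_m)},
\]
whose diagonal is \(0.5(1+\hat f_i)\) (self-kinship with excess-homozygosity
inbreeding) and for which \(2K\) is positive semi-definite by construction.
Monomorphic markers are skipped.

`fit_polygenic()` fits \(y = X\beta + g + e\), \(g \sim N(0, 2K\sigma^2_g)\),
\(e \sim N(0, I\sigma^2_e)\) by restricted maximum likelihood. A single
eigendecomposition of \(2K\) reduces the profiled REML criterion to a
one-dimensional optimisation over \(h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)\)
(Brent search on \((10^{-6}, 1-10^{-6})\), tolerance `1e-8`); total variance
and fixed effects are closed-form at each \(h^2\). When the kinship
eigenvalues are numerically constant (e.g. \(K = 0.5I\), no relatedness) the
variance split is unidentifiable; the fit falls back to ordinary least
squares and is flagged `identifiable = FALSE` rather than reporting an
arbitrary split.

Association testing follows the two-step family-based design (the
FASTA/GRAMMAR strategy): variance components are estimated once per cohort
on the null model and reused for every variant. `score_test()` then computes
the exact GLS estimate for a coded genotype \(c\) (covariate-adjusted under
the \(V^{-1}\) inner product, \(V = 2K\hat\sigma^2_g + I\hat\sigma^2_e\)):
\(\hat\beta = c^\top V^{-1} y^* / (c^\top V^{-1} c)\),
\(\mathrm{se} = (c^\top V^{-1} c)^{-1/2}\), with a two-sided normal p-value.
Published two-step implementations differ in whether per-variant effects are
exact GLS or an approximation; the exact-GLS contract was chosen because it
is sharply testable — the suite checks it against a brute-force dense-matrix
GLS oracle to `1e-8` — and because it reduces to OLS exactly when
\(\sigma^2_g = 0\) (the reported standard error then uses the null-model
residual variance, the hallmark of the two-step design, rather than the
per-variant alternative-model variance).

## Genotype coding and variant filters

The coded (effect) allele is always `a1`; recoding to the other allele is an
explicit operation, never implicit. With imputed data the package codes by
expectation over the genotype posterior: additive = dosage, recessive =
\(P(\text{hom-}a_1)\), dominant = \(P(\text{het}) + P(\text{hom-}a_1)\)
(`code_genotype()`). This extends the expectation principle by which dosage
generalises hard-call additive coding; thresholding to a best-guess genotype
is available (`recessive_coding = "hardcall"`) for comparison. Requesting a
non-additive code for fractional dosages without genotype probabilities is
an error, not a silent rounding.

Three filters precede testing, all strict inequalities as conventionally
printed: minor-allele frequency < 0.01 fails; imputation quality below the
per-cohort cut fails (INFO < 0.4 for IMPUTE-style pipelines, R² < 0.3 for
MaCH/minimac-style — which metric the stored `info` field means is a
per-cohort decision); and the coded-category frequency (mean code divided by
its maximum, e.g. the coded-homozygote frequency under the recessive model)
outside (0.01, 0.99) fails, since nearly-empty categories destabilise the
test. `run_scan()` composes QC, coding, filtering and the score test for
every variant under every requested model, reusing one null fit.

## Meta-analysis, genomic control, thresholds, replication

`inverse_variance_meta()` pools per-cohort estimates with weights
\(1/\mathrm{se}^2\). The arithmetic is deliberately model-agnostic — the
motivation for implementing it in-package is that standard GWAS
meta-analysis tools assume additive coding, while the identical formula
serves dominant and recessive summary statistics. Genomic control
(`genomic_control()`) computes \(\lambda = \mathrm{median}(\chi^2) /
\mathrm{qchisq}(0.5, 1)\) on the post-meta statistics (the order the
pipeline prescribes: meta-analysis first, then control) and deflates only
when \(\lambda > 1\). The genome-wide threshold divides the conventional
5e-8 by the effective number of model tests, 2.2, giving 2.27e-8
(`significance_threshold()`); 2.2 is treated as an input constant from the
multiple-genetic-models literature, not re-derived.

A discovery hit replicates when the replication p is strictly below 0.05
with a sign-concordant effect after allele harmonisation
(`replication_filter()`), and `pool_all_cohorts()` then pools discovery and
replication; on the bundled PDSS2 locus table exactly 5 of the printed
variants replicate and every one pools to a p below its discovery p. The
bundled table preserves all 28 printed rows as published (the accompanying
text counts 21 genome-wide-significant SNPs; the table prints 28; the
package keeps the table as printed and does not resolve the discrepancy).
Its positions were printed at 0.1-Mb resolution and are stored as base
pairs at that resolution — which is why position-based allele harmonisation
should not be run against this particular table.

## eQTL pattern comparison

To ask whether a GWAS signal and a gene's cis-eQTL signal share a source,
each variant in the locus window (default the recombination-hotspot
delimited chr6:107,400,000–107,900,000, inclusive on both ends) gets a
signed score \(s = \mathrm{sign}(\hat\beta)\,(-\log_{10} p)\), and the GWAS
and per-tissue eQTL score vectors are compared by Kendall rank correlation
(`compare_all_tissues()`). Kendall's τ-b (tie-corrected) is used: published
descriptions of this comparison rarely state the tie policy, real signed
scores rarely tie, and τ-b is the safe general choice. The significance
test is the standard one for τ (exact enumeration for small untied samples,
normal approximation otherwise); the "correlation test" is read as the test
of τ itself, not a separate Pearson test. Effect alleles are harmonised on
(chrom, pos, allele set) with sign flips for swapped alleles;
strand-ambiguous A/T and C/G pairs are excluded unless
`assume_same_strand = TRUE`, appropriate when both sources are aligned to
the same reference.

## The simulator: what it emulates, and what it does not

`simulate_cohort()` generates nuclear families (two founders plus
`1 + Poisson(mean_sibs - 1)` sibs), founder genotypes in Hardy–Weinberg
equilibrium, offspring by per-locus Mendelian gene-dropping, and a
phenotype built on the latent `log10(cups + 1)` scale:

latent = intercept + Σ causal effects (under each causal variant's model
coding) + polygenic value + sex and age effects + N(0, σe²),

with the polygenic value propagated through the pedigree (founders
\(N(0, \sigma^2_g)\), offspring mid-parent plus segregation variance
\(\sigma^2_g/2\), \(\sigma^2_g = h^2/(1-h^2)\,\sigma^2_e\)). Cup counts are
the deterministic inverse `max(round(10^latent - 1), 0)` rather than a
Poisson draw, so the causal β stays exactly interpretable on the analysis
scale; the integer rounding behaves as extra measurement noise and
attenuates estimated effects by roughly 5–10% at the default intercept,
visible in the recovery study below. Imputation-like dosages come from
blending each hard-call genotype-probability triplet with the
Hardy–Weinberg background; the blend weight is solved in closed form so the
realised INFO — defined as `var(dosage) / (2 p (1 - p))`, one of several
published definitions, chosen because it is computable from dosages alone —
matches the target.

Default conditions (all in `sim_config()`): intercept 0.45 on the log10
scale (≈ 1.8 cups, matching Italian-style consumption), residual sd 0.18,
polygenic h² 0.3 (twin heritability estimates for coffee consumption run
0.36–0.58, part of which a non-null simulation assigns to the causal
variant), sex effect 0.05, age effect 0.002 per year centred at 50, age
uniform on [18, 80], sex Bernoulli(0.5), 5% on hypertensive medication
independent of genotype. With these choices a recessive β of 0.086 at
coded-homozygote frequency 0.3 and n ≈ 1200 yields a standard error of
about 0.014 — the scale reported for discovery cohorts of that size.

The simulator deliberately omits: linkage disequilibrium beyond family
co-inheritance (no coalescent haplotypes), population stratification,
multi-generation pedigrees, and the X chromosome. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean family
model, not robustness to LD structure or stratification in real data.

## Study sizes and numerical choices in the verification suite

The test suite and acceptance report use sizes chosen to make Monte-Carlo
error small relative to the tested tolerances while keeping a full run in
minutes: null calibration uses one cohort of ~1200 samples and 2000
variants with 25–50 independent null phenotype redraws (genotypes and
kinship shared across redraws; type-I error and λ are pooled over the
~50–100k resulting tests, and the type-I bound accounts for within-redraw
correlation via the empirical between-redraw variance); effect recovery
uses 60–100 independent cohorts of the same size. Variance-component
parameter recovery is checked against the pedigree-expected kinship
(`pedigree_kinship()`), the exact covariance of the simulated polygenic
term; genomic kinship from a small marker panel estimates that matrix with
noise of the same order as the h² signal when markers ≈ samples, which
biases variance components toward zero — a known property of
marker-estimated relationship matrices, and why real analyses estimate
kinship from hundreds of thousands of genotyped SNPs. Association
calibration is insensitive to this (the calibration study above runs
entirely on genomic kinship).

Other numerical conventions: p-values are two-sided normal throughout
(large-sample score tests); genotype-probability triplets must sum to 1
within 1e-6 and match dosages within 1e-6, violations raise rather than
repair; missing dosages are not supported (drop samples upstream);
positions are 1-based; fixed-effect meta only (no heterogeneity model;
Cochran's Q available as an optional diagnostic column); both homozygote
codings are not scanned automatically — coding is always with respect to
`a1`.

## Known limitations

- Exact GLS per variant is O(n²) after the one-off eigendecomposition;
  cohorts beyond ~10⁴ samples would want the approximate GRAMMAR-style
  residual shortcut, which is not implemented.
- The coded-category filter uses the mean coded value; under strong
  imputation uncertainty this differs from the hard-call category count.
- Single-component variance model only; no dominance variance component,
  no gene–environment interactions.
- The replication and pooling logic assumes summary statistics on the same
  trait scale across cohorts; no cross-cohort trait rescaling is attempted.
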