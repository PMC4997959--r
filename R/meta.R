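#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools effect estimates with weights `w_i = 1 / se_i^2`:
#' `beta_pooled = sum(w beta) / sum(w)`, `se_pooled = 1 / sqrt(sum(w))`,
#' p two-sided normal. The arithmetic is identical whatever the genetic
#' model of the inputs — the point of rolling it by hand is precisely
#' that dominant- and recessive-model summary statistics pool the same
#' way as additive ones.
#'
#' @param beta,se Numeric vectors of per-cohort estimates and standard
#'   errors (all `se > 0`).
#' @return One-row tibble `beta, se, p, n_studies`.
#' @export
inverse_variance_meta <- function(beta, se) {
  if (length(beta) == 0) stop("no studies to pool", call. = FALSE)
  if (length(beta) != length(se)) stop("beta and se lengths differ", call. = FALSE)
  if (any(se <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  sp <- 1 / sqrt(sum(w))
  tibble::tibble(beta = bp, se = sp, p = 2 * stats::pnorm(-abs(bp / sp)),
                 n_studies = length(beta))
}

#' Meta-analyse per-cohort association results
#'
#' Joins cohort result tibbles by variant and model and pools each
#' (variant, model) present in every cohort by
#' [inverse_variance_meta()]. Order-invariant in the cohorts.
#'
#' @param ... Association tibbles (schema of [sumstats]), one per cohort,
#'   optionally named; names become cohort labels.
#' @param require_all_cohorts Drop variants missing from any cohort
#'   (default; mirrors discarding variants that fail QC in more than one
#'   population).
#' @param heterogeneity Add Cochran's Q and its p-value as diagnostic
#'   columns.
#' @return Meta tibble `snp, chrom, pos, a0, a1, model, beta, se, p,
#'   n_studies` (+ `q, q_p`), sorted by model then input variant order of
#'   the first cohort.
#' @export
meta_analyse <- function(..., require_all_cohorts = TRUE,
                         heterogeneity = FALSE) {
  cohorts <- list(...)
  if (length(cohorts) == 1 && is.list(cohorts[[1]]) &&
      !is.data.frame(cohorts[[1]])) {
    cohorts <- cohorts[[1]]
  }
  if (length(cohorts) == 0) stop("no cohorts given", call. = FALSE)
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  stacked <- dplyr::bind_rows(cohorts, .id = "cohort")
  grouped <- dplyr::group_by(stacked, .data$snp, .data$model)
  pooled <- dplyr::summarise(
    grouped,
    chrom = dplyr::first(.data$chrom), pos = dplyr::first(.data$pos),
    a0 = dplyr::first(.data$a0), a1 = dplyr::first(.data$a1),
    q = sum((1 / .data$se^2) *
              (.data$beta - sum(.data$beta / .data$se^2) / sum(1 / .data$se^2))^2),
    beta = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
    se = 1 / sqrt(sum(1 / .data$se^2)),
    n_studies = dplyr::n(),
    .groups = "drop"
  )
  pooled <- dplyr::mutate(pooled, p = 2 * stats::pnorm(-abs(.data$beta / .data$se)))
  if (require_all_cohorts) {
    pooled <- dplyr::filter(pooled, .data$n_studies == length(cohorts))
  }
  if (heterogeneity) {
    pooled <- dplyr::mutate(pooled,
                            q_p = stats::pchisq(.data$q, pmax(.data$n_studies - 1, 1),
                                                lower.tail = FALSE))
  } else {
    pooled$q <- NULL
  }
  first <- cohorts[[1]]
  pooled <- dplyr::arrange(
    pooled, .data$model,
    match(.data$snp, unique(first$snp))
  )
  dplyr::relocate(pooled, "snp", "chrom", "pos", "a0", "a1", "model",
                  "beta", "se", "p")
}

#' Genomic control
#'
#' Computes the inflation factor `lambda = median(chisq) / qchisq(0.5, 1)`
#' from the per-variant association statistics `chisq = (beta / se)^2`.
#' When `lambda > 1` every statistic is deflated by it — standard errors
#' inflate by `sqrt(lambda)` and p-values are recomputed; `lambda <= 1`
#' leaves the results untouched. `lambda` is recorded either way in the
#' `lambda_applied` column (and as the `"lambda"` attribute).
#'
#' @param results Association or meta tibble with `beta` and `se`.
#' @return The (possibly corrected) tibble with a `lambda_applied`
#'   column.
#' @export
genomic_control <- function(results) {
  if (is.null(results) || nrow(results) == 0) stop("no results", call. = FALSE)
  if (nrow(results) < 100) {
    warning("genomic control on fewer than 100 statistics is unstable",
            call. = FALSE)
  }
  chisq <- (results$beta / results$se)^2
  lambda <- stats::median(chisq, na.rm = TRUE) / stats::qchisq(0.5, 1)
  out <- results
  if (is.finite(lambda) && lambda > 1) {
    out$se <- out$se * sqrt(lambda)
    out$p <- 2 * stats::pnorm(-abs(out$beta / out$se))
  }
  out$lambda_applied <- lambda
  attr(out, "lambda") <- lambda
  out
}

#' Genome-wide significance threshold under multiple genetic models
#'
#' Running several correlated genetic models per variant multiplies the
#' effective number of tests; the conventional genome-wide level is
#' divided by that effective count (2.2 for the
#' additive/dominant/recessive triple), giving 5e-8 / 2.2 = 2.27e-8.
#'
#' @param alpha_gw Conventional genome-wide level (default 5e-8).
#' @param n_eff_models Effective number of model tests (default 2.2).
#' @return List with `alpha_gw`, `n_eff_models`, `threshold`.
#' @export
significance_threshold <- function(alpha_gw = 5e-8, n_eff_models = 2.2) {
  if (alpha_gw <= 0 || n_eff_models <= 0) {
    stop("alpha_gw and n_eff_models must be positive", call. = FALSE)
  }
  list(alpha_gw = alpha_gw, n_eff_models = n_eff_models,
       threshold = alpha_gw / n_eff_models)
}

#' Replication verdicts for discovery hits
#'
#' A discovery hit replicates when its replication-cohort p-value is
#' strictly below `alpha` *and* the replication effect has the same sign
#' as the discovery effect. Alleles are harmonised before comparison
#' (replication rows whose effect allele is the discovery other-allele
#' have their sign flipped); discovery rows with no replication match
#' are kept with `NA` verdicts and listed in the `"unmatched"` attribute.
#'
#' @param discovery Tibble with `snp, model?, a0, a1, beta, se, p`.
#' @param replication Tibble with `snp, (a0, a1,) beta, se, p` from the
#'   replication cohort.
#' @param alpha Replication level (default 0.05).
#' @return `discovery` plus `beta_rep, se_rep, p_rep,
#'   direction_concordant, replicated`.
#' @export
replication_filter <- function(discovery, replication, alpha = 0.05) {
  clash <- intersect(c("beta_rep", "se_rep", "p_rep", "a0_rep", "a1_rep"),
                     names(discovery))
  if (length(clash) > 0) {
    stop("discovery already carries replication column(s): ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  rep_cols <- replication[, intersect(c("snp", "model", "a0", "a1", "beta", "se", "p"),
                                      names(replication))]
  names(rep_cols) <- sub("^(beta|se|p|a0|a1)$", "\\1_rep", names(rep_cols))
  by <- intersect(c("snp", "model"), intersect(names(discovery), names(replication)))
  merged <- dplyr::left_join(discovery, rep_cols, by = by)
  if (all(c("a0_rep", "a1_rep") %in% names(merged))) {
    swapped <- !is.na(merged$a1_rep) & merged$a1_rep == merged$a0 &
      merged$a0_rep == merged$a1
    incompatible <- !is.na(merged$a1_rep) & !swapped &
      !(merged$a1_rep == merged$a1 & merged$a0_rep == merged$a0)
    merged$beta_rep[swapped] <- -merged$beta_rep[swapped]
    merged$beta_rep[incompatible] <- NA_real_
    merged$p_rep[incompatible] <- NA_real_
    merged$a0_rep <- merged$a1_rep <- NULL
  }
  merged <- dplyr::mutate(
    merged,
    direction_concordant = sign(.data$beta_rep) == sign(.data$beta),
    replicated = .data$p_rep < alpha & .data$direction_concordant
  )
  attr(merged, "unmatched") <- merged$snp[is.na(merged$p_rep)]
  merged
}

#' Pool discovery and replication cohorts
#'
#' Final inverse-variance pooling over all cohorts for each variant
#' (e.g. the discovery meta-estimate together with the replication
#' cohort), flagging whether the pooled p improves on the discovery p.
#'
#' @param results Tibble with one row per variant carrying discovery
#'   (`beta, se, p`) and replication (`beta_rep, se_rep`) columns, e.g.
#'   the output of [replication_filter()].
#' @return `results` plus `beta_pooled, se_pooled, p_pooled,
#'   improves_discovery`.
#' @export
pool_all_cohorts <- function(results) {
  pooled <- purrr::pmap(
    list(results$beta, results$se, results$beta_rep, results$se_rep),
    function(b, s, br, sr) {
      if (is.na(br) || is.na(sr)) {
        return(tibble::tibble(beta_pooled = NA_real_, se_pooled = NA_real_,
                              p_pooled = NA_real_))
      }
      m <- inverse_variance_meta(c(b, br), c(s, sr))
      tibble::tibble(beta_pooled = m$beta, se_pooled = m$se, p_pooled = m$p)
    })
  dplyr::mutate(dplyr::bind_cols(results, dplyr::bind_rows(pooled)),
                improves_discovery = .data$p_pooled < .data$p)
}
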