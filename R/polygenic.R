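#' Fit the polygenic null mixed model
#'
#' Restricted maximum likelihood for `y = X b + g + e` with
#' `g ~ N(0, 2K sigma_g^2)` and `e ~ N(0, I sigma_e^2)`: the
#' heritability `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` is profiled by
#' one-dimensional optimisation after a single eigendecomposition of
#' `2K`, with the total variance and the fixed effects solved in closed
#' form at each `h2`. This is the two-step family-based design
#' (FASTA/GRAMMAR): the null model is fitted once per cohort and its
#' variance components are reused for every variant's score test.
#'
#' @param y Response vector (transformed trait), length n.
#' @param X Fixed-effect design matrix, n x p (see [build_design()]).
#' @param kinship A `kinship_matrix` over the same samples (same order).
#' @param h2_tol Convergence tolerance of the heritability optimisation.
#' @return A `polygenic_fit` with variance components (`sigma2_g`,
#'   `sigma2_e`, `h2`), GLS `fixed_effects`, raw GLS `residuals`,
#'   `vinv_residuals` (`V^-1 (y - X b)`), the restricted `loglik`, and
#'   the cached spectral pieces used by [score_test()]. When the kinship
#'   eigenvalues are (numerically) constant — e.g. `K = 0.5 I`, no
#'   relatedness — the variance split is non-identifiable: the fit
#'   reduces to ordinary least squares and is flagged
#'   `identifiable = FALSE`.
#' @export
fit_polygenic <- function(y, X, kinship, h2_tol = 1e-8) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || length(kinship$samples) != n) {
    stop("dimensions of y, X and kinship disagree", call. = FALSE)
  }
  A <- 2 * kinship$K
  if (max(abs(A - t(A))) > 1e-8) stop("kinship matrix not symmetric", call. = FALSE)
  eg <- eigen(A, symmetric = TRUE)
  lambda <- eg$values
  if (min(lambda) < -1e-8 * max(abs(lambda))) {
    stop("2K is not positive semi-definite; regularize the kinship diagonal",
         call. = FALSE)
  }
  lambda <- pmax(lambda, 0)
  U <- eg$vectors
  ty <- drop(crossprod(U, y))
  tX <- crossprod(U, X)
  p <- ncol(X)

  profile <- function(h2) {
    d <- h2 * lambda + (1 - h2)
    w <- 1 / d
    XtWX <- crossprod(tX, w * tX)
    beta <- solve(XtWX, crossprod(tX, w * ty))
    r <- ty - drop(tX %*% beta)
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(s2) + sum(log(d)) +
                    determinant(XtWX, logarithm = TRUE)$modulus[1] +
                    (n - p))
    list(h2 = h2, loglik = ll, beta = drop(beta), s2 = s2, d = d, w = w,
         XtWX = XtWX, resid_rot = r)
  }

  identifiable <- (max(lambda) - min(lambda)) > 1e-8
  if (identifiable) {
    opt <- stats::optimize(function(h) profile(h)$loglik,
                           interval = c(1e-6, 1 - 1e-6),
                           maximum = TRUE, tol = h2_tol)
    sol <- profile(opt$maximum)
  } else {
    sol <- profile(0)
  }
  resid <- y - drop(X %*% sol$beta)
  vinv_resid <- drop(U %*% (sol$w * sol$resid_rot)) / sol$s2
  fe <- sol$beta
  names(fe) <- colnames(X)
  structure(list(
    sigma2_g = sol$h2 * sol$s2,
    sigma2_e = (1 - sol$h2) * sol$s2,
    h2 = sol$h2,
    sigma2_total = sol$s2,
    fixed_effects = fe,
    residuals = resid,
    vinv_residuals = vinv_resid,
    loglik = sol$loglik,
    identifiable = identifiable,
    n = n,
    samples = kinship$samples,
    .spectral = list(U = U, lambda = lambda, w = sol$w, ty = ty, tX = tX,
                     resid_rot = sol$resid_rot, XtWX = sol$XtWX)
  ), class = "polygenic_fit")
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat(sprintf("<polygenic_fit> n = %d, h2 = %.3f (sigma2_g = %.4g, sigma2_e = %.4g)%s\n",
              x$n, x$h2, x$sigma2_g, x$sigma2_e,
              if (x$identifiable) "" else " [variance split non-identifiable]"))
  cat("fixed effects:\n"); print(x$fixed_effects)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a polygenic fit
#'
#' @param x A `polygenic_fit`.
#' @param ... Unused.
#' @return Tibble of fixed-effect estimates.
#' @method tidy polygenic_fit
#' @export
tidy.polygenic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$fixed_effects),
                 estimate = unname(x$fixed_effects))
}

#' @rdname tidy.polygenic_fit
#' @return `glance`: one-row tibble of variance components and fit summary.
#' @method glance polygenic_fit
#' @export
glance.polygenic_fit <- function(x, ...) {
  tibble::tibble(n = x$n, h2 = x$h2, sigma2_g = x$sigma2_g,
                 sigma2_e = x$sigma2_e, loglik = x$loglik,
                 identifiable = x$identifiable)
}

#' Mixed-model score test of one coded genotype vector
#'
#' Exact generalised-least-squares association test at the null-model
#' variance components: with `V = 2K sigma_g^2 + I sigma_e^2` and `c` the
#' covariate-adjusted code (`c = g - X (X' V^-1 X)^-1 X' V^-1 g`),
#' `beta = c' V^-1 y / (c' V^-1 c)`, `se = 1 / sqrt(c' V^-1 c)`, and the
#' p-value is two-sided normal on `beta / se`. Equals the joint GLS
#' estimate of the genotype coefficient alongside the covariates; reduces
#' to ordinary least squares when `sigma_g^2 = 0`.
#'
#' @param coded_genotype Numeric vector, the model-coded genotype (see
#'   [code_genotype()]), same sample order as the fit.
#' @param fit A [fit_polygenic()] object.
#' @return One-row tibble `beta, se, p, n, testable`; a code with no
#'   variance left after covariate adjustment is flagged untestable
#'   (`beta`, `se`, `p` all `NA`).
#' @export
score_test <- function(coded_genotype, fit) {
  if (length(coded_genotype) != fit$n) {
    stop("coded genotype length does not match the fitted model", call. = FALSE)
  }
  res <- score_test_matrix(matrix(coded_genotype, ncol = 1), fit)
  tibble::tibble(beta = res$beta, se = res$se, p = res$p, n = fit$n,
                 testable = res$testable)
}

# Vectorised score tests: C is n x m of coded genotypes.
score_test_matrix <- function(C, fit) {
  sp <- fit$.spectral
  tC <- crossprod(sp$U, C)
  gamma <- solve(sp$XtWX, crossprod(sp$tX, sp$w * tC))
  tCadj <- tC - sp$tX %*% gamma
  s2 <- fit$sigma2_total
  ctvic <- colSums(sp$w * tCadj^2) / s2
  ctviy <- drop(crossprod(tCadj, sp$w * sp$resid_rot)) / s2
  scale_ref <- colSums(sp$w * tC^2) / s2 + 1e-300
  testable <- ctvic > 1e-10 * pmax(scale_ref, fit$n)
  beta <- ifelse(testable, ctviy / ctvic, NA_real_)
  se <- ifelse(testable, 1 / sqrt(ctvic), NA_real_)
  p <- ifelse(testable, 2 * stats::pnorm(-abs(beta / se)), NA_real_)
  list(beta = beta, se = se, p = p, testable = testable)
}
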