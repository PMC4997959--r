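#' Expected kinship from a pedigree
#'
#' Kinship coefficients implied by the pedigree alone (no genotype
#' noise): recursively, `phi(i, j) = (phi(father_i, j) + phi(mother_i,
#' j)) / 2` for a non-founder `i` with `j` preceding it, founders
#' mutually unrelated, and `phi(i, i) = 0.5 (1 + f_i)` with `f_i` the
#' kinship of `i`'s parents. For the nuclear families produced by
#' [simulate_pedigree()] this gives 0.25 for sib and parent-offspring
#' pairs, 0 across families and for founder couples, diagonal 0.5. This
#' is the exact covariance structure of the simulator's polygenic term,
#' so it is the reference matrix for variance-component
#' parameter-recovery checks; genomic kinship from a finite marker panel
#' estimates it with noise.
#'
#' @param pedigree Tibble with `id`, `father`, `mother` (parents must
#'   precede children).
#' @return A `kinship_matrix`.
#' @export
pedigree_kinship <- function(pedigree) {
  n <- nrow(pedigree)
  fi <- match(pedigree$father, pedigree$id)
  mi <- match(pedigree$mother, pedigree$id)
  idx <- seq_len(n)
  if (any(fi >= idx, na.rm = TRUE) || any(mi >= idx, na.rm = TRUE)) {
    stop("parents must precede children in the pedigree", call. = FALSE)
  }
  K <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      K[i, i] <- 0.5
    } else {
      for (j in seq_len(i - 1)) {
        K[i, j] <- K[j, i] <- (K[fi[i], j] + K[mi[i], j]) / 2
      }
      K[i, i] <- 0.5 * (1 + K[fi[i], mi[i]])
    }
    if (is.na(fi[i])) {
      for (j in seq_len(i - 1)) K[i, j] <- K[j, i] <- 0  # founders unrelated
    }
  }
  structure(list(samples = pedigree$id, K = K, n_variants = NA_integer_),
            class = "kinship_matrix")
}
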