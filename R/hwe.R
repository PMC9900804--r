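#' Exact Hardy-Weinberg and excess-heterozygosity tests
#'
#' Conditions on the observed allele counts: with `n` diploids and `na`
#' copies of the rarer allele, the number of heterozygotes `h` under
#' Hardy-Weinberg equilibrium follows
#' P(h) = C * n! 2^h / (((na - h)/2)! h! (n - (na + h)/2)!),
#' over h with the parity of na. `hwe_p` is the two-sided exact probability:
#' the sum of P over all configurations no more probable than the observed
#' one. `exchet_p` is the one-sided probability of at least the observed
#' heterozygote count (small values flag heterozygote excess, a lifted-over
#' or batch artifact signal).
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts, total >= 1
#' @return list with `hwe_p` and `exchet_p`
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(length(n_hom_ref) == 1, length(n_het) == 1, length(n_hom_alt) == 1)
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("negative genotype count")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("no called genotypes: all three counts are zero")
  na <- n_het + 2L * min(n_hom_ref, n_hom_alt)  # rarer-allele copies
  h_obs <- n_het
  hs <- seq(na %% 2L, min(na, 2L * n - na), by = 2L)
  logp <- lfactorial(n) + hs * log(2) -
    lfactorial((na - hs) / 2) - lfactorial(hs) - lfactorial(n - (na + hs) / 2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[match(h_obs, hs)]
  list(
    hwe_p = min(1, sum(p[p <= p_obs * (1 + 1e-9)])),
    exchet_p = min(1, sum(p[hs >= h_obs]))
  )
}

#' Per-variant genotype counts and exact-test probabilities
#'
#' @param ds genotype_dataset
#' @return data.frame with n_hom_ref, n_het, n_hom_alt, hwe_p, exchet_p
#' @export
hwe_test_dataset <- function(ds) {
  d <- ds$dosages
  n0 <- rowSums(d == 0L, na.rm = TRUE)
  n1 <- rowSums(d == 1L, na.rm = TRUE)
  n2 <- rowSums(d == 2L, na.rm = TRUE)
  res <- mapply(function(a, h, b) {
    if (a + h + b < 1) return(c(NA_real_, NA_real_))
    p <- hwe_exact_test(a, h, b)
    c(p$hwe_p, p$exchet_p)
  }, n0, n1, n2)
  data.frame(n_hom_ref = n0, n_het = n1, n_hom_alt = n2,
             hwe_p = res[1, ], exchet_p = res[2, ])
}
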