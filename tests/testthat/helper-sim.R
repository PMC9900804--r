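# Shared fixture builders (everything generated in code; no stored data).

# Hand-specifiable dataset: `geno` is a variants x samples matrix.
make_ds <- function(geno, pop = NULL, region = NULL, phased = FALSE,
                    hap1 = NULL, hap2 = NULL, pos = NULL, ref = NULL,
                    alt = NULL, extra_samples = NULL) {
  nv <- nrow(geno); ns <- ncol(geno)
  variants <- data.frame(
    contig = "chr1",
    pos = if (is.null(pos)) 1000L * seq_len(nv) else pos,
    ref = if (is.null(ref)) rep("A", nv) else ref,
    alt = if (is.null(alt)) rep("G", nv) else alt,
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(ns)),
    population = if (is.null(pop)) "P1" else pop,
    region = if (is.null(region)) "AFR" else region,
    stringsAsFactors = FALSE)
  if (!is.null(extra_samples)) {
    for (nm in names(extra_samples)) samples[[nm]] <- extra_samples[[nm]]
  }
  genotype_dataset(variants, samples, geno, hap1 = hap1, hap2 = hap2,
                   phased = phased)
}

# Random small cohort for recount-style oracles.
random_ds <- function(nv = 50, ns = 20, maf_range = c(0.1, 0.5),
                      missing_rate = 0, seed = 1) {
  set.seed(seed)
  p <- runif(nv, maf_range[1], maf_range[2])
  g <- matrix(rbinom(nv * ns, 2L, p), nv, ns)
  if (missing_rate > 0) g[runif(nv * ns) < missing_rate] <- NA_integer_
  make_ds(g)
}

two_pop_cfg <- function(f = 0.1, n = 50, nv = 2000, seed = 1, ...) {
  sim_config(populations = list(
    pop_spec("A", "AFR", n, f, 7.4, 3.9),
    pop_spec("B", "EUR", n, f, 52.1, 5.1)),
    n_variants = nv, seed = seed, ...)
}

# Brute-force maximum/maximal independent set checks on small graphs.
is_independent <- function(ids, edges) {
  !any(edges$i %in% ids & edges$j %in% ids &
         mapply(function(a, b) a %in% ids && b %in% ids, edges$i, edges$j))
}
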