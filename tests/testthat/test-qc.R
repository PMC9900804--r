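# independent enumeration oracle: genotype-configuration probabilities
# conditional on allele counts, via the closed form
# P(h) = n! / (nAA! h! naa!) * 2^h * na! * nb! / (2n)!
hwe_enum_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_alt + n_het
  nb <- 2 * n - na
  hs <- seq(na %% 2, min(na, nb), by = 2)
  p <- vapply(hs, function(h) {
    naa <- (na - h) / 2
    nbb <- n - naa - h
    factorial(n) / (factorial(naa) * factorial(h) * factorial(nbb)) *
      2^h * factorial(na) * factorial(nb) / factorial(2 * n)
  }, 1)
  stopifnot(abs(sum(p) - 1) < 1e-9)  # oracle self-check: proper distribution
  obs <- p[match(n_het, hs)]
  list(hwe_p = min(1, sum(p[p <= obs * (1 + 1e-9)])),
       exchet_p = min(1, sum(p[hs >= n_het])))
}

test_that("exact HWE/ExcHet matches full enumeration for all small configs", {
  for (n in c(3, 10, 30)) {
    for (naa in 0:min(n, 5)) {
      for (h in seq(0, n - naa, by = max(1, (n - naa) %/% 4))) {
        nbb <- n - naa - h
        got <- hwe_exact_test(nbb, h, naa)
        want <- hwe_enum_oracle(nbb, h, naa)
        expect_equal(got$hwe_p, want$hwe_p, tolerance = 1e-9)
        expect_equal(got$exchet_p, want$exchet_p, tolerance = 1e-9)
      }
    }
  }
})

test_that("HWE exact test handles modal and extreme configurations", {
  expect_error(hwe_exact_test(0, 0, 0), "no called genotypes")
  perfect <- hwe_exact_test(25, 50, 25)
  expect_equal(perfect$hwe_p, 1, tolerance = 1e-9)
  expect_gte(perfect$exchet_p, 0.5)
  # all-hom split at p = 0.5: astronomically unlikely under HWE
  # (oracle limited to 2n <= 170 by double-precision factorials)
  extreme <- hwe_exact_test(35, 0, 35)
  want <- hwe_enum_oracle(35, 0, 35)
  expect_equal(extreme$hwe_p, want$hwe_p, tolerance = 1e-6)
  expect_lt(extreme$hwe_p, 1e-18)
  expect_equal(extreme$exchet_p, 1)
  expect_lt(hwe_exact_test(50, 0, 50)$hwe_p, 1e-25)
})

test_that("relatedness_pca filter enforces open MAF interval and strict missingness", {
  # 10 samples; craft AF exactly 0.05 (AC=1/AN=20), inside, and monomorphic
  g <- rbind(c(1, rep(0, 9)),              # AF 0.05 exactly -> removed
             c(1, 1, 1, 1, rep(0, 6)),     # AF 0.2 -> kept
             rep(0, 10),                   # monomorphic -> removed
             c(NA, 1, 1, rep(0, 7)))       # 10% missing -> removed
  ds <- make_ds(g)
  res <- filter_variants(ds, mode = "relatedness_pca")
  expect_equal(nrow(res$dataset$variants), 1L)
  expect_equal(res$dataset$variants$pos, 2000L)
  expect_equal(res$report$rule,
               c("snv_only", "maf_open_interval", "missingness"))
  # idempotent
  res2 <- filter_variants(res$dataset, mode = "relatedness_pca")
  expect_equal(res2$dataset$dosages, res$dataset$dosages)
  expect_equal(sum(res2$report$removed), 0L)
})

test_that("planted filter violations match a set-logic oracle", {
  set.seed(31)
  nv <- 1000; ns <- 40
  p <- runif(nv, 0.2, 0.5)
  low_maf <- sample(nv, 50)
  p[low_maf] <- 0.01
  g <- matrix(rbinom(nv * ns, 2L, p), nv, ns)
  high_miss <- sample(nv, 30)  # may overlap low_maf
  g[high_miss, 1:4] <- NA_integer_
  ds <- make_ds(g)
  th <- qc_thresholds(max_missing = 0.05)
  res <- filter_variants(ds, th, mode = "relatedness_pca")
  # oracle: recompute the surviving set directly
  af <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
  fmiss <- rowMeans(is.na(g))
  keep <- af > 0.05 & af < 0.95 & fmiss < 0.05
  expect_equal(nrow(res$dataset$variants), sum(keep))
  expect_equal(variant_keys(res$dataset), variant_keys(ds)[keep])
})

test_that("phasing_prep filter applies HWE, F_MISSING and ExcHet in order", {
  set.seed(7)
  ns <- 150
  g <- matrix(rbinom(20 * ns, 2L, 0.3), 20, ns)
  g[1, ] <- rep(c(0L, 2L), ns / 2)  # opposite homozygotes only: hwe_p < 1e-30
  # mild het excess: passes the (very permissive) HWE bound, fails ExcHet
  g[2, ] <- c(rep(1L, 88), rep(0L, 31), rep(2L, 31))
  g[3, 1:50] <- NA_integer_         # 33% missing
  ds <- make_ds(g)
  res <- filter_variants(ds, mode = "phasing_prep")
  expect_equal(res$report$rule, c("hwe", "f_missing", "exchet"))
  kept <- variant_keys(res$dataset)
  expect_false(variant_keys(ds)[1] %in% kept)  # hwe_p << 1e-30
  expect_false(variant_keys(ds)[3] %in% kept)  # f_missing > 0.1
  expect_false(variant_keys(ds)[2] %in% kept)
  ex <- hwe_exact_test(31, 88, 31)
  expect_gte(ex$hwe_p, 1e-30)
  expect_lt(ex$exchet_p, 0.5)
})

test_that("ld_prune removes duplicated columns and honours its contract", {
  set.seed(13)
  base <- rbinom(60, 2L, 0.4)
  g <- rbind(base, base, matrix(rbinom(5 * 60, 2L, 0.4), 5, 60))
  ds <- make_ds(g)
  kept <- ld_prune(ds, window = 500000, r2_max = 0.1)
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)  # identical variant 1 kb away: r2 = 1
})

test_that("independent variants survive pruning at the null r2 scale", {
  ds <- random_ds(nv = 300, ns = 200, seed = 17)
  kept <- ld_prune(ds, window = 500000, r2_max = 0.1)
  expect_gte(length(kept) / 300, 0.99)
})

test_that("no retained in-window pair reaches the r2 threshold (brute force)", {
  cfg <- sim_config(populations = list(pop_spec("P", "AFR", 60, 0.05, 0, 0)),
                    n_variants = 200, ld_block_size = 8,
                    ld_copy_error = 0.05, seed = 23)
  ds <- simulate_genotypes(cfg)
  kept <- ld_prune(ds, window = 20000, r2_max = 0.1)
  expect_lt(length(kept), 200)  # blocks actually pruned
  v <- ds$variants
  for (a in seq_along(kept)) {
    for (b in seq_len(a - 1L)) {
      ia <- kept[a]; ib <- kept[b]
      if (abs(v$pos[ia] - v$pos[ib]) > 20000) next
      r <- cor(ds$dosages[ia, ], ds$dosages[ib, ],
               use = "pairwise.complete.obs")
      expect_lt(r^2, 0.1)
    }
  }
})

test_that("sample_stats matches a brute-force recount and singleton identity", {
  ds <- random_ds(nv = 50, ns = 20, missing_rate = 0.05, seed = 41)
  ds$variants$variant_class[1:10] <- "indel"
  st <- sample_stats(ds)
  d <- ds$dosages
  for (j in c(1, 7, 20)) {
    snv <- ds$variants$variant_class == "SNV"
    expect_equal(st$n_snv[j], sum(d[snv, j] > 0, na.rm = TRUE))
    expect_equal(st$n_indel[j], sum(d[!snv, j] > 0, na.rm = TRUE))
    expect_equal(st$call_rate[j], mean(!is.na(d[, j])))
  }
  # singleton total over samples = count of AC=1 variants
  expect_equal(sum(st$n_singleton),
               sum(ds$variants$allele_count == 1L))
  # a reference-identical sample
  g <- matrix(c(0L, 0L, 0L, 1L), 2, 2)
  st2 <- sample_stats(make_ds(g))
  expect_equal(st2$n_snv[1], 0L)
  expect_equal(st2$call_rate[1], 1)
  expect_equal(st2$n_singleton, c(0L, 1L))
})

test_that("group_summary arithmetic, zero-sd and singleton groups", {
  df <- data.frame(v = c(1, 2, 3, 4, 5, 9),
                   population = c("a", "a", "a", "b", "b", "c"))
  gs <- group_summary(df, "v", "population")
  expect_equal(gs$mean, c(2, 4.5, 9))
  expect_equal(gs$sd[1], 1)
  expect_true(is.na(gs$sd[3]))  # single-sample group
  gs2 <- group_summary(data.frame(v = rep(2, 4),
                                  population = c("a", "a", "b", "b")),
                       "v", "population")
  expect_equal(gs2$sd, c(0, 0))
  expect_error(group_summary(df, "nope", "population"), "unknown metric")
})

test_that("downsample_singletons subsets, drops monomorphics and skips small pops", {
  cfg <- sim_config(populations = list(
    pop_spec("big", "AFR", 10, 0.05, 0, 0),
    pop_spec("tiny", "EUR", 3, 0.05, 10, 10)),
    n_variants = 500, seed = 19)
  ds <- simulate_genotypes(cfg)
  expect_warning(
    res <- downsample_singletons(ds, unrelated_ids = ds$samples$sample_id,
                                 n_per_pop = 4, seed = 2),
    "tiny")
  expect_equal(res$skipped, "tiny")
  expect_equal(nrow(res$per_sample), 4L)
  # post-condition: no monomorphic variants remain in the counted subset
  sub <- subset_dataset(ds, sample_ids = res$per_sample$sample_id)
  sub <- filter_variants(sub, mode = "monomorphic_only")$dataset
  expect_equal(sum(res$per_sample$n_singleton),
               sum(sub$variants$allele_count == 1L))
  # population with exactly 4 unrelateds: subset equals population
  cfg2 <- sim_config(populations = list(pop_spec("four", "AFR", 4, 0.05, 0, 0)),
                     n_variants = 200, seed = 3)
  ds2 <- simulate_genotypes(cfg2)
  res2 <- downsample_singletons(ds2, ds2$samples$sample_id, seed = 1)
  expect_setequal(res2$per_sample$sample_id, ds2$samples$sample_id)
})

test_that("higher-diversity populations carry more singletons", {
  mean_singletons <- function(spread_lo, f, seed) {
    cfg <- sim_config(populations = list(pop_spec("P", "AFR", 8, f, 0, 0)),
                      n_variants = 800,
                      ancestral_freq_range = c(spread_lo, 0.5), seed = seed)
    ds <- simulate_genotypes(cfg)
    res <- downsample_singletons(ds, ds$samples$sample_id, n_per_pop = 4,
                                 seed = seed)
    res$per_population$mean
  }
  # wide ancestral MAF spread + low drift vs narrow spread + heavy drift
  wins <- sum(vapply(1:8, function(s)
    mean_singletons(0.01, 0.02, s) > mean_singletons(0.25, 0.3, s), TRUE))
  expect_gte(wins, 6)  # sign test across seeds
})
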