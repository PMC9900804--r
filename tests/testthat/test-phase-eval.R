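phased_ds <- function(h1, h2, pos = NULL) {
  make_ds(h1 + h2, phased = TRUE, hap1 = h1, hap2 = h2, pos = pos)
}

test_that("switch error rate: identity, global flip, and the hand example", {
  cfg <- sim_config(populations = list(pop_spec("P", "AFR", 10, 0.05, 0, 0)),
                    n_variants = 300, seed = 91)
  truth <- simulate_genotypes(cfg)
  expect_equal(switch_error_rate(truth, truth)$mean_ser, 0)
  flipped <- truth
  flipped$hap1 <- truth$hap2
  flipped$hap2 <- truth$hap1
  expect_equal(switch_error_rate(truth, flipped)$mean_ser, 0)
  # orientations truth [a,a,a,a] vs test [a,b,b,a]: 2 switches / 3 pairs
  t1 <- matrix(c(1L, 1L, 1L, 1L), 4, 1)
  t2 <- matrix(c(0L, 0L, 0L, 0L), 4, 1)
  truth1 <- phased_ds(t1, t2)
  test1 <- phased_ds(matrix(c(1L, 0L, 0L, 1L), 4, 1),
                     matrix(c(0L, 1L, 1L, 0L), 4, 1))
  rep1 <- switch_error_rate(truth1, test1)
  expect_equal(rep1$per_sample$n_het_pairs, 3L)
  expect_equal(rep1$per_sample$n_switches, 2L)
  expect_equal(rep1$per_sample$switch_error_rate, 2 / 3)
})

test_that("switch counting is invariant to variant-order permutation", {
  cfg <- sim_config(populations = list(pop_spec("P", "AFR", 8, 0.05, 0, 0)),
                    n_variants = 200, seed = 92)
  truth <- simulate_genotypes(cfg)
  test <- corrupt_haplotypes(truth, 0.2, seed = 7)
  base <- switch_error_rate(truth, test)
  set.seed(3)
  perm <- sample(200)
  shuf <- function(ds) {
    ds$variants <- ds$variants[perm, ]
    ds$dosages <- ds$dosages[perm, , drop = FALSE]
    ds$hap1 <- ds$hap1[perm, , drop = FALSE]
    ds$hap2 <- ds$hap2[perm, , drop = FALSE]
    recompute_allele_counts(ds)
  }
  again <- switch_error_rate(shuf(truth), shuf(test))
  expect_equal(again$per_sample$n_switches, base$per_sample$n_switches)
})

test_that("sites unusable in the test break the pair chain", {
  t1 <- matrix(1L, 5, 1); t2 <- matrix(0L, 5, 1)
  truth <- phased_ds(t1, t2)
  # site 3 homozygous in test: pairs (2,3) and (3,4) are both lost
  h1 <- matrix(c(1L, 1L, 0L, 1L, 1L), 5, 1)
  h2 <- matrix(c(0L, 0L, 0L, 0L, 0L), 5, 1)
  test <- make_ds(h1 + h2, phased = TRUE, hap1 = h1, hap2 = h2)
  rep <- switch_error_rate(truth, test)
  expect_equal(rep$per_sample$n_het_pairs, 2L)  # (1,2) and (4,5)
  expect_equal(rep$per_sample$n_skipped, 1L)
  expect_equal(rep$per_sample$n_switches, 0L)
})

test_that("corruption at a known switch rate is recovered within 3 SE", {
  cfg <- sim_config(populations = list(pop_spec("P", "AFR", 60, 0.01, 0, 0)),
                    n_variants = 2500, ancestral_freq_range = c(0.2, 0.5),
                    seed = 93)
  truth <- simulate_genotypes(cfg)
  test <- corrupt_haplotypes(truth, 0.1, seed = 11)
  rep <- switch_error_rate(truth, test)
  n_pairs <- sum(rep$per_sample$n_het_pairs)
  se <- sqrt(0.1 * 0.9 / n_pairs)
  measured <- sum(rep$per_sample$n_switches) / n_pairs
  expect_lt(abs(measured - 0.1), 3 * se)
  # full corruption flips every consecutive het pair
  rep1 <- switch_error_rate(truth, corrupt_haplotypes(truth, 1, seed = 2))
  expect_equal(rep1$mean_ser, 1)
})

test_that("switch errors split by variant class", {
  cfg <- sim_config(populations = list(pop_spec("P", "AFR", 6, 0.05, 0, 0)),
                    n_variants = 400, seed = 94)
  truth <- simulate_genotypes(cfg)
  truth$variants$ref[1:200] <- "AT"        # mark half as indels
  truth$variants$variant_class[1:200] <- "indel"
  test <- corrupt_haplotypes(truth, 0.3, seed = 5)
  test$variants <- truth$variants
  rep <- switch_error_rate(truth, test)
  expect_setequal(unique(rep$by_class$variant_class), c("SNV", "indel"))
  expect_equal(nrow(rep$by_class), 12L)
})

test_that("aggregate r2 equals a naive flat-loop oracle and handles degeneracy", {
  cfg <- two_pop_cfg(n = 20, nv = 500, seed = 95)
  cfg$ancestral_freq_range <- c(0.02, 0.5)
  truth <- simulate_genotypes(cfg)
  imp <- simulate_imputed_dosages(truth, 1, seed = 4)
  edges <- c(0.01, 0.05, 0.5)
  tab <- aggregate_r2(truth, imp, bin_edges = edges)
  maf <- variant_maf(truth)
  bin <- cut(maf, c(0, edges))
  for (b in seq_along(levels(bin))) {
    rows <- which(!is.na(bin) & as.integer(bin) == b)
    if (length(rows) == 0) next
    x <- c(); y <- c()
    for (v in rows) for (j in seq_len(ncol(truth$dosages))) {
      if (!is.na(truth$dosages[v, j]) && !is.na(imp[v, j])) {
        x <- c(x, truth$dosages[v, j]); y <- c(y, imp[v, j])
      }
    }
    expect_equal(tab$r2[b], cor(x, y)^2, tolerance = 1e-12)
  }
  # exact imputation -> r2 = 1; constant imputation -> undefined, not 0
  exact <- aggregate_r2(truth, truth$dosages, bin_edges = edges)
  expect_true(all(exact$r2[exact$n_variants > 0] == 1))
  const <- aggregate_r2(truth, matrix(1, 500, 40), bin_edges = edges)
  expect_true(all(is.na(const$r2)))
  expect_error(aggregate_r2(truth, imp[1:10, ]), "shape")
})

test_that("replicates average and panels compare with signed deltas", {
  cfg <- two_pop_cfg(n = 15, nv = 400, seed = 96)
  truth <- simulate_genotypes(cfg)
  edges <- c(0.05, 0.5)
  reps <- list(simulate_imputed_dosages(truth, 1, seed = 1),
               simulate_imputed_dosages(truth, 1, seed = 2))
  tab <- aggregate_r2(truth, reps, bin_edges = edges)
  expect_equal(tab$r2, rowMeans(cbind(tab$rep1, tab$rep2)))
  good <- aggregate_r2(truth, simulate_imputed_dosages(truth, 4, seed = 3),
                       bin_edges = edges)
  bad <- aggregate_r2(truth, simulate_imputed_dosages(truth, 0.5, seed = 3),
                      bin_edges = edges)
  rep_cmp <- panel_comparison_report(list(low_noise = good, high_noise = bad))
  expect_equal(nrow(rep_cmp), 4L)
  self <- rep_cmp[rep_cmp$panel == "low_noise", ]
  expect_true(all(self$delta_vs_baseline == 0))
  other <- rep_cmp[rep_cmp$panel == "high_noise", ]
  ok <- !is.na(other$delta_vs_baseline)
  expect_true(all(other$delta_vs_baseline[ok] <= 0))
})
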