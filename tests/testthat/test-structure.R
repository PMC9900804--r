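make_pca_input <- function(cfg) {
  ds <- simulate_genotypes(cfg)
  list(ds = ds,
       qc = filter_variants(ds, qc_thresholds(max_missing = 1),
                            mode = "relatedness_pca")$dataset)
}

test_that("PC1 separates two diverged populations completely", {
  inp <- make_pca_input(two_pop_cfg(f = 0.05, n = 100, nv = 3000, seed = 51))
  pm <- fit_pca(inp$qc, k = 4)
  pc1 <- pm$scores_train[, 1]
  popA <- inp$ds$samples$population == "A"
  expect_true(max(pc1[popA]) < min(pc1[!popA]) ||
                min(pc1[popA]) > max(pc1[!popA]))
  expect_true(all(diff(pm$eigenvalues) <= 1e-8))
  expect_true(all(pm$eigenvalues > 0))
})

test_that("scores equal normalized matrix times loadings; sign is canonical", {
  inp <- make_pca_input(two_pop_cfg(f = 0.05, n = 30, nv = 400, seed = 52))
  pm <- fit_pca(inp$qc, k = 5)
  p <- pm$af
  x <- t((inp$qc$dosages - 2 * p) / sqrt(2 * p * (1 - p)))
  x[is.na(x)] <- 0
  expect_equal(unname(x %*% pm$loadings), unname(pm$scores_train),
               tolerance = 1e-8)
  for (c in 1:5) {
    expect_gt(pm$loadings[which.max(abs(pm$loadings[, c])), c], 0)
  }
  # sample-order invariance up to the fixed sign convention
  perm <- rev(seq_len(nrow(inp$qc$samples)))
  pm2 <- fit_pca(subset_dataset(inp$qc,
                                sample_ids = inp$qc$samples$sample_id[perm]),
                 k = 5)
  expect_equal(pm2$scores_train[rownames(pm$scores_train), ],
               pm$scores_train, tolerance = 1e-6)
})

test_that("PCA input validation: k bound and monomorphic variants", {
  ds <- random_ds(nv = 20, ns = 10, seed = 53)
  expect_error(fit_pca(ds, k = 11), "exceeds")
  g <- ds$dosages
  g[1, ] <- 0L
  expect_error(fit_pca(make_ds(g), k = 3), "monomorphic")
})

test_that("projection reproduces training scores and compensates masking", {
  inp <- make_pca_input(two_pop_cfg(f = 0.1, n = 40, nv = 2000, seed = 54))
  pm <- fit_pca(inp$qc, k = 5)
  pr <- project_samples(pm, inp$qc)
  expect_equal(pr$scores[pm$sample_ids, ], pm$scores_train,
               tolerance = 1e-6)
  expect_true(all(pr$observed_fraction == 1))
  # mask 20% of one training sample's genotypes: rescaling keeps it close
  one <- subset_dataset(inp$qc, sample_ids = pm$sample_ids[1])
  set.seed(9)
  hide <- sample(nrow(one$variants), round(0.2 * nrow(one$variants)))
  one$dosages[hide, 1] <- NA_integer_
  prm <- project_samples(pm, one)
  expect_equal(prm$observed_fraction[[1]], 0.8, tolerance = 0.001)
  rel <- sqrt(sum((prm$scores - pm$scores_train[1, ])^2)) /
    sqrt(sum(pm$scores_train[1, ]^2))
  expect_lt(rel, 0.35)
  # and it stays nearest its own original score among all training samples
  d2 <- colSums((t(pm$scores_train) - as.vector(prm$scores))^2)
  expect_equal(names(which.min(d2)), pm$sample_ids[1])
  expect_error(project_samples(pm, mask_to_sites(inp$ds, "chr1:1:A:G")),
               "no variants|no overlap")
})

test_that("a third population projects away from both training clusters", {
  cfg <- sim_config(populations = list(
    pop_spec("A", "AFR", 40, 0.05, 0, 0),
    pop_spec("B", "EUR", 40, 0.05, 10, 10),
    pop_spec("C", "EAS", 20, 0.3, 20, 20)),
    n_variants = 2000, seed = 55)
  ds <- simulate_genotypes(cfg)
  qc <- filter_variants(ds, qc_thresholds(max_missing = 1),
                        mode = "relatedness_pca")$dataset
  train <- subset_dataset(qc, sample_ids = qc$samples$sample_id[
    qc$samples$population %in% c("A", "B")])
  train <- filter_variants(train, mode = "monomorphic_only")$dataset
  pm <- fit_pca(train, k = 4)
  ext <- subset_dataset(qc, sample_ids = qc$samples$sample_id[
    qc$samples$population == "C"])
  pr <- project_samples(pm, ext)
  expect_true(all(pr$observed_fraction == 1))
  centroidA <- colMeans(pm$scores_train[train$samples$population == "A", ])
  centroidB <- colMeans(pm$scores_train[train$samples$population == "B", ])
  centroidC <- colMeans(pr$scores)
  # C sits well off both training centroids relative to their separation
  sep <- sqrt(sum((centroidA - centroidB)^2))
  expect_gt(sqrt(sum((centroidC - centroidA)^2)), 0.3 * sep)
  expect_gt(sqrt(sum((centroidC - centroidB)^2)), 0.3 * sep)
})

test_that("ancestry model learns separable regions and rejects degenerate input", {
  cfg <- sim_config(populations = list(
    pop_spec("A", "AFR", 40, 0.1, 0, 0),
    pop_spec("B", "EUR", 40, 0.1, 10, 10),
    pop_spec("C", "EAS", 40, 0.1, 20, 20)),
    n_variants = 2000, seed = 56)
  ds <- simulate_genotypes(cfg)
  qc <- filter_variants(ds, qc_thresholds(max_missing = 1),
                        mode = "relatedness_pca")$dataset
  pm <- fit_pca(qc, k = 6)
  # held-out split
  set.seed(1)
  test_idx <- unlist(lapply(split(seq_len(120), qc$samples$region),
                            sample, 10))
  am <- train_ancestry_model(pm$scores_train[-test_idx, ],
                             qc$samples$region[-test_idx], seed = 3)
  probs <- predict(am$forest,
                   as.data.frame(pm$scores_train[test_idx, 1:am$n_pcs]),
                   type = "prob")
  acc <- mean(am$levels[max.col(probs)] == qc$samples$region[test_idx])
  expect_gte(acc, 0.95)
  # permuted labels: no signal
  set.seed(2)
  am0 <- train_ancestry_model(pm$scores_train,
                              sample(qc$samples$region), seed = 3)
  expect_lt(am0$oob_accuracy, 0.6)
  expect_error(train_ancestry_model(pm$scores_train,
                                    rep("X", 120)), "two ancestry labels")
  # determinism under a fixed seed
  am2 <- train_ancestry_model(pm$scores_train[-test_idx, ],
                              qc$samples$region[-test_idx], seed = 3)
  expect_identical(predict(am$forest, as.data.frame(
    pm$scores_train[test_idx, 1:am$n_pcs])),
    predict(am2$forest, as.data.frame(
      pm$scores_train[test_idx, 1:am2$n_pcs])))
})

test_that("assign_ancestry labels planted-truth samples and flags uncertainty", {
  cfg <- sim_config(populations = list(
    pop_spec("A", "AFR", 50, 0.1, 0, 0),
    pop_spec("B", "EUR", 50, 0.1, 10, 10)),
    n_variants = 2000, seed = 57)
  ds <- simulate_genotypes(cfg)
  qc <- filter_variants(ds, qc_thresholds(max_missing = 1),
                        mode = "relatedness_pca")$dataset
  train_ids <- qc$samples$sample_id[c(1:40, 51:90)]
  ext_ids <- setdiff(qc$samples$sample_id, train_ids)
  train <- filter_variants(subset_dataset(qc, sample_ids = train_ids),
                           mode = "monomorphic_only")$dataset
  pm <- fit_pca(train, k = 4)
  am <- train_ancestry_model(pm$scores_train, train$samples$region, seed = 5)
  ext <- subset_dataset(qc, sample_ids = ext_ids)
  asg <- assign_ancestry(am, pm, ext)
  expect_equal(asg$label, ext$samples$region)
  expect_false(any(asg$low_confidence))
  # an impossible probability bar yields "uncertain", never a forced label
  asg2 <- assign_ancestry(am, pm, ext, prob_threshold = 1.01)
  expect_true(all(asg2$label == "uncertain"))
})

test_that("missingness sweep degrades monotonically in expectation", {
  cfg <- sim_config(populations = list(
    pop_spec("A", "AFR", 40, 0.1, 0, 0),
    pop_spec("B", "EUR", 40, 0.1, 10, 10),
    pop_spec("C", "EAS", 40, 0.1, 20, 20)),
    n_variants = 1500, seed = 58)
  ds <- simulate_genotypes(cfg)
  qc <- filter_variants(ds, qc_thresholds(max_missing = 1),
                        mode = "relatedness_pca")$dataset
  pm <- fit_pca(qc, k = 6)
  am <- train_ancestry_model(pm$scores_train, qc$samples$region, seed = 7)
  sweep <- missingness_sweep(am, pm, qc, qc$samples$region,
                             mask_grid = c(0, 0.05, 0.5), seeds = 1:2)
  expect_equal(nrow(sweep), 6L)  # |grid| x |seeds|
  base <- assign_ancestry(am, pm, qc)
  expect_equal(sweep$accuracy[sweep$mask_fraction == 0][1],
               mean(base$label == qc$samples$region))
  m <- tapply(sweep$accuracy, sweep$mask_fraction, mean)
  expect_gte(m["0.05"], m["0.5"] - 1e-9)
})
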