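#' HWE-normalized PCA
#'
#' Each genotype is centered and scaled by its expected Hardy-Weinberg
#' moments, (g - 2p) / sqrt(2 p (1 - p)) with p the alternate-allele
#' frequency among the training samples; missing genotypes become 0 after
#' centering (mean imputation). The top-k singular decomposition of the
#' normalized samples-by-variants matrix gives training scores (U D),
#' variant loadings (V) and eigenvalues (squared singular values). The sign
#' of each component is fixed by making its largest-magnitude loading
#' positive, so results are invariant to sample ordering.
#'
#' Input should be LD-pruned common variants from unrelated samples;
#' monomorphic variants are an error (filter first).
#'
#' @param ds genotype_dataset
#' @param k number of components (default 20)
#' @param max_missing tolerated overall missing fraction before a warning
#'   that mean imputation may distort the space (default 0.05)
#' @return object of class `pca_model`: `variant_keys`, `af`, `loadings`
#'   (variants x k), `eigenvalues`, `scores_train` (samples x k),
#'   `sample_ids`, `k`
#' @export
fit_pca <- function(ds, k = 20, max_missing = 0.05) {
  d <- ds$dosages
  if (k > min(dim(d))) {
    stop("k = ", k, " exceeds min(n_variants, n_samples) = ", min(dim(d)))
  }
  an <- ds$variants$allele_number
  p <- ifelse(an > 0, ds$variants$allele_count / an, NA_real_)
  if (any(is.na(p) | p <= 0 | p >= 1)) {
    stop(sum(is.na(p) | p <= 0 | p >= 1),
         " monomorphic or uncalled variants in PCA input; ",
         "apply filter_variants() first")
  }
  fmiss <- mean(is.na(d))
  if (fmiss > max_missing) {
    warning(sprintf(
      "%.1f%% of training genotypes are missing; mean imputation may distort the PC space",
      100 * fmiss))
  }
  x <- t((d - 2 * p) / sqrt(2 * p * (1 - p)))  # samples x variants
  x[is.na(x)] <- 0
  sv <- svd(x, nu = k, nv = k)
  dvals <- sv$d[seq_len(k)]
  loadings <- sv$v
  scores <- sv$u %*% diag(dvals, k)
  flip <- vapply(seq_len(k), function(c)
    sign(loadings[which.max(abs(loadings[, c])), c]), 1)
  loadings <- sweep(loadings, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  rownames(scores) <- ds$samples$sample_id
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(variant_keys = variant_keys(ds), af = p,
                 loadings = loadings, eigenvalues = dvals^2,
                 scores_train = scores, sample_ids = ds$samples$sample_id,
                 k = k),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model:", length(x$variant_keys), "variants,",
      length(x$sample_ids), "training samples,", x$k, "components\n")
  ev <- x$eigenvalues / sum(x$eigenvalues)
  cat("  top eigenvalue shares:",
      paste(sprintf("%.3f", utils::head(ev, 5)), collapse = " "), "\n")
  invisible(x)
}

#' Project new samples into an existing PC space
#'
#' New genotypes are normalized with the model's stored training allele
#' frequencies and multiplied onto the loadings. Model variants absent from
#' the new dataset, or missing in a sample, are skipped, and each sample's
#' score is rescaled by (number of model variants) / (number observed for
#' that sample) to compensate; the observed fraction is reported so callers
#' can flag low-overlap projections. No shrinkage correction is applied.
#'
#' @param model pca_model
#' @param ds_new genotype_dataset sharing variant keys with the model
#' @return list: `scores` (samples x k), `observed_fraction` per sample
#' @export
project_samples <- function(model, ds_new) {
  keys_new <- variant_keys(ds_new)
  idx_model <- match(keys_new, model$variant_keys)
  present <- !is.na(idx_model)
  if (!any(present)) stop("no overlap between dataset and model variants")
  d <- ds_new$dosages[present, , drop = FALSE]
  p <- model$af[idx_model[present]]
  ld <- model$loadings[idx_model[present], , drop = FALSE]
  xn <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  obs <- !is.na(xn)
  xn[!obs] <- 0
  scores <- t(xn) %*% ld
  n_obs <- colSums(obs)
  n_model <- length(model$variant_keys)
  scores <- scores * (n_model / n_obs)
  rownames(scores) <- ds_new$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores, observed_fraction = n_obs / n_model)
}

#' Train a random-forest ancestry classifier on PC scores
#'
#' @param scores samples x PCs matrix (e.g. `model$scores_train`)
#' @param labels region (or population) labels, one per row of `scores`
#' @param n_pcs number of leading PCs used as features (default up to 20)
#' @param ntree number of trees (default 500)
#' @param seed integer seed (forest growth is seeded, hence deterministic)
#' @return object of class `ancestry_model`: the forest, label levels,
#'   `n_pcs`, out-of-bag accuracy
#' @export
train_ancestry_model <- function(scores, labels, n_pcs = min(20, ncol(scores)),
                                 ntree = 500, seed = 1) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two ancestry labels")
  if (any(table(labels) < 2)) stop("every label needs at least two samples")
  n_pcs <- min(n_pcs, ncol(scores))
  x <- as.data.frame(scores[, seq_len(n_pcs), drop = FALSE])
  set.seed(seed)
  rf <- randomForest::randomForest(x, labels, ntree = ntree)
  oob <- mean(rf$predicted == labels)
  structure(list(forest = rf, levels = levels(labels), n_pcs = n_pcs,
                 oob_accuracy = oob, seed = seed),
            class = "ancestry_model")
}

#' @export
print.ancestry_model <- function(x, ...) {
  cat("ancestry_model: random forest on", x$n_pcs, "PCs,",
      length(x$levels), "labels (", paste(x$levels, collapse = ", "), ")\n")
  cat(sprintf("  out-of-bag accuracy: %.3f\n", x$oob_accuracy))
  invisible(x)
}

#' Assign ancestry labels to external samples
#'
#' Projects the external dataset into the reference PC space, applies the
#' classifier, and reports per-label probabilities. A sample whose maximum
#' probability falls below `prob_threshold` is labelled `"uncertain"`
#' rather than forced; samples observing less than
#' `1 - missingness_tolerance` of the model variants are flagged low
#' confidence (high missingness degrades projection accuracy; below ~5%
#' missingness assignments are typically reliable).
#'
#' @param am ancestry_model
#' @param pca_model pca_model the classifier was trained in
#' @param ds_external genotype_dataset to label
#' @param prob_threshold minimum winning probability (default 0.5)
#' @param missingness_tolerance observed-fraction slack before flagging
#'   (default 0.05)
#' @return data.frame: sample_id, label, max_prob, observed_fraction,
#'   low_confidence, plus one probability column per class
#' @export
assign_ancestry <- function(am, pca_model, ds_external,
                            prob_threshold = 0.5,
                            missingness_tolerance = 0.05) {
  pr <- project_samples(pca_model, ds_external)
  x <- as.data.frame(pr$scores[, seq_len(am$n_pcs), drop = FALSE])
  probs <- stats::predict(am$forest, x, type = "prob")
  winner <- am$levels[max.col(probs, ties.method = "first")]
  max_prob <- apply(probs, 1, max)
  label <- ifelse(max_prob < prob_threshold, "uncertain", winner)
  out <- data.frame(sample_id = ds_external$samples$sample_id,
                    label = label, max_prob = max_prob,
                    observed_fraction = pr$observed_fraction,
                    low_confidence =
                      pr$observed_fraction < 1 - missingness_tolerance,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(probs))
}

#' Ancestry accuracy as a function of masking
#'
#' Masks the external dataset's genotypes uniformly at each fraction in
#' `mask_grid` (per seed), reassigns labels, and records accuracy against
#' the known truth, quantifying how much missingness label transfer
#' tolerates.
#'
#' @param am ancestry_model
#' @param pca_model pca_model
#' @param ds_external genotype_dataset with known labels
#' @param truth_labels true label per external sample
#' @param mask_grid masking fractions (default 0, 0.05, 0.1, 0.2, 0.5)
#' @param seeds integer seeds (default 1:3)
#' @param prob_threshold passed to [assign_ancestry()]
#' @return data.frame: mask_fraction, seed, accuracy, n_uncertain
#' @export
missingness_sweep <- function(am, pca_model, ds_external, truth_labels,
                              mask_grid = c(0, 0.05, 0.1, 0.2, 0.5),
                              seeds = 1:3, prob_threshold = 0.5) {
  stopifnot(length(truth_labels) == nrow(ds_external$samples))
  rows <- list()
  for (s in seeds) {
    for (m in mask_grid) {
      dsm <- ds_external
      if (m > 0) {
        set.seed(s * 1000L + round(1000 * m))
        hide <- matrix(stats::runif(length(dsm$dosages)) < m,
                       nrow = nrow(dsm$dosages))
        dsm$dosages[hide] <- NA_integer_
        if (!is.null(dsm$hap1)) { dsm$hap1[hide] <- NA_integer_
                                  dsm$hap2[hide] <- NA_integer_ }
        dsm <- recompute_allele_counts(dsm)
      }
      asg <- assign_ancestry(am, pca_model, dsm,
                             prob_threshold = prob_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        mask_fraction = m, seed = s,
        accuracy = mean(asg$label == truth_labels),
        n_uncertain = sum(asg$label == "uncertain"))
    }
  }
  do.call(rbind, rows)
}
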