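#' Switch error rate against truth haplotypes
#'
#' Both datasets must be phased and share samples and variant keys. Per
#' sample, truth-heterozygous sites are ordered by position; at each site
#' that is also heterozygous and called in the test set, the phase
#' orientation (whether the test's first haplotype carries the same allele
#' as the truth's first haplotype) is compared between consecutive usable
#' sites, and a switch is counted when the orientation flips. A global
#' haplotype swap of a whole sample flips every orientation and therefore
#' counts no switch. Truth-het sites that are homozygous or missing in the
#' test break the chain: no pair is counted across them. Rates are reported
#' per sample, overall, and split by variant class; a compound flip at one
#' site registers as two switches (no flip-aware decomposition).
#'
#' @param truth,test phased genotype_dataset objects on identical samples
#'   and variant keys
#' @return object of class `switch_error_report`: `per_sample` data.frame
#'   (sample_id, n_het_pairs, n_switches, switch_error_rate, n_skipped),
#'   `by_class` (the same split by SNV/indel), `mean_ser`, `sd_ser`
#' @export
switch_error_rate <- function(truth, test) {
  if (!truth$phased || !test$phased) stop("both datasets must be phased")
  if (!identical(truth$samples$sample_id, test$samples$sample_id)) {
    stop("sample sets differ between truth and test")
  }
  if (!identical(variant_keys(truth), variant_keys(test))) {
    stop("variant keys differ between truth and test")
  }
  ord <- order(truth$variants$contig, truth$variants$pos)
  vclass <- truth$variants$variant_class
  per_sample <- list()
  by_class_rows <- list()
  for (j in seq_along(truth$samples$sample_id)) {
    res_all <- count_switches(truth, test, j, ord)
    per_sample[[j]] <- data.frame(
      sample_id = truth$samples$sample_id[j],
      n_het_pairs = res_all$n_pairs, n_switches = res_all$n_switches,
      switch_error_rate = if (res_all$n_pairs > 0)
        res_all$n_switches / res_all$n_pairs else NA_real_,
      n_skipped = res_all$n_skipped, stringsAsFactors = FALSE)
    for (cl in unique(vclass)) {
      res <- count_switches(truth, test, j, ord[vclass[ord] == cl])
      by_class_rows[[paste(j, cl)]] <- data.frame(
        sample_id = truth$samples$sample_id[j], variant_class = cl,
        n_het_pairs = res$n_pairs, n_switches = res$n_switches,
        switch_error_rate = if (res$n_pairs > 0)
          res$n_switches / res$n_pairs else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  ps <- do.call(rbind, per_sample)
  bc <- do.call(rbind, by_class_rows)
  rownames(bc) <- NULL
  structure(list(per_sample = ps, by_class = bc,
                 mean_ser = mean(ps$switch_error_rate, na.rm = TRUE),
                 sd_ser = stats::sd(ps$switch_error_rate)),
            class = "switch_error_report")
}

# orientation walk over one sample's truth-het sites (ord: candidate
# variant indices in position order)
count_switches <- function(truth, test, j, ord) {
  th <- ord[!is.na(truth$dosages[ord, j]) & truth$dosages[ord, j] == 1L]
  usable <- !is.na(test$dosages[th, j]) & test$dosages[th, j] == 1L
  us <- which(usable)
  if (length(us) < 2) {
    return(list(n_pairs = 0L, n_switches = 0L, n_skipped = sum(!usable)))
  }
  v <- th[us]
  orient <- test$hap1[v, j] == truth$hap1[v, j]
  # only adjacent truth-het sites form a pair: a skipped site breaks the chain
  adjacent <- diff(us) == 1L
  flipped <- orient[-1] != orient[-length(orient)]
  list(n_pairs = sum(adjacent),
       n_switches = sum(adjacent & flipped),
       n_skipped = sum(!usable))
}

#' @export
print.switch_error_report <- function(x, ...) {
  cat(sprintf("switch error rate: mean %.5f (sd %.5f) over %d samples\n",
              x$mean_ser, x$sd_ser, nrow(x$per_sample)))
  cls <- split(x$by_class, x$by_class$variant_class)
  for (cl in names(cls)) {
    cat(sprintf("  %s: mean %.5f\n", cl,
                mean(cls[[cl]]$switch_error_rate, na.rm = TRUE)))
  }
  invisible(x)
}

#' Aggregate imputation r-squared in MAF bins
#'
#' Pools every (truth genotype, imputed dosage) pair over the variants of a
#' MAF bin and reports the squared Pearson correlation - the standard
#' imputation-accuracy summary. Bins with zero variance on either side (or
#' fewer than two pairs) are reported as NA, never zero-filled. Several
#' imputed replicates may be supplied; their per-bin r-squared values are
#' averaged with a dispersion column.
#'
#' @param truth genotype_dataset or numeric truth-dosage matrix
#' @param imputed numeric matrix in \[0, 2\] matching `truth`, or a list of
#'   such matrices (replicates)
#' @param maf per-variant minor allele frequencies used for binning; when
#'   NULL and `truth` is a dataset, the truth-cohort MAF is used
#' @param bin_edges increasing MAF bin edges in (0, 0.5]
#'   (default 1e-4, 1e-3, 0.01, 0.05, 0.5)
#' @param pool pool genotype pairs within a bin (default TRUE, the
#'   aggregate convention); FALSE averages per-variant r-squared instead
#' @return data.frame of class `aggregate_r2_table`: bin, n_variants,
#'   r2 (replicate mean), r2_sd, plus one column per replicate
#' @export
aggregate_r2 <- function(truth, imputed, maf = NULL,
                         bin_edges = c(1e-4, 1e-3, 0.01, 0.05, 0.5),
                         pool = TRUE) {
  tm <- if (inherits(truth, "genotype_dataset")) truth$dosages else truth
  if (is.null(maf)) {
    if (!inherits(truth, "genotype_dataset")) {
      stop("maf must be supplied when truth is a plain matrix")
    }
    maf <- variant_maf(truth)
  }
  reps <- if (is.list(imputed) && !is.data.frame(imputed)) imputed
          else list(imputed)
  for (r in reps) {
    if (!all(dim(r) == dim(tm))) stop("imputed matrix shape mismatch")
  }
  stopifnot(length(maf) == nrow(tm))
  bin <- cut(maf, c(0, bin_edges), include.lowest = FALSE)
  bin_r2 <- function(imp, rows) {
    if (length(rows) == 0) return(NA_real_)
    if (pool) {
      x <- as.vector(tm[rows, , drop = FALSE])
      y <- as.vector(imp[rows, , drop = FALSE])
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        return(NA_real_)
      }
      stats::cor(x[ok], y[ok])^2
    } else {
      vals <- vapply(rows, function(v) {
        x <- tm[v, ]; y <- imp[v, ]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
          return(NA_real_)
        }
        stats::cor(x[ok], y[ok])^2
      }, 1)
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }
  }
  lev <- levels(bin)
  out <- data.frame(bin = lev,
                    n_variants = as.integer(table(bin)),
                    stringsAsFactors = FALSE)
  rep_cols <- vapply(reps, function(imp)
    vapply(lev, function(l) bin_r2(imp, which(!is.na(bin) & bin == l)), 1),
    numeric(length(lev)))
  rep_cols <- matrix(rep_cols, nrow = length(lev))
  colnames(rep_cols) <- paste0("rep", seq_along(reps))
  out$r2 <- rowMeans(rep_cols, na.rm = TRUE)
  out$r2[is.nan(out$r2)] <- NA_real_
  out$r2_sd <- if (length(reps) > 1) apply(rep_cols, 1, stats::sd) else NA_real_
  out <- cbind(out, as.data.frame(rep_cols))
  class(out) <- c("aggregate_r2_table", "data.frame")
  out
}

#' Side-by-side comparison of evaluation panels
#'
#' Takes two or more named [aggregate_r2()] tables on identical bins and
#' reports per-bin values, deltas against the first (baseline) panel, and
#' the bins where each panel crosses above the baseline.
#'
#' @param evaluations named list of `aggregate_r2_table` objects
#' @return data.frame: bin, panel, r2, delta_vs_baseline, crosses_baseline
#' @export
panel_comparison_report <- function(evaluations) {
  stopifnot(length(evaluations) >= 2, !is.null(names(evaluations)))
  base <- evaluations[[1]]
  rows <- list()
  for (nm in names(evaluations)) {
    ev <- evaluations[[nm]]
    if (!identical(ev$bin, base$bin)) {
      stop("panel ", nm, " uses different MAF bins than the baseline")
    }
    rows[[nm]] <- data.frame(
      bin = ev$bin, panel = nm, r2 = ev$r2,
      delta_vs_baseline = ev$r2 - base$r2,
      crosses_baseline = !is.na(ev$r2) & !is.na(base$r2) & ev$r2 > base$r2,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
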