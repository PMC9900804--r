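#' QC thresholds
#'
#' Defaults follow the study pipeline: the relatedness/PCA site filter keeps
#' SNVs with MAF strictly between `maf_min` and `maf_max` and per-variant
#' missing fraction strictly below `max_missing`; LD pruning uses a 500 kb
#' window at r^2 < 0.1; the pre-phasing filter keeps variants with exact HWE
#' p >= 1e-30, missing fraction <= 0.1 and exact excess-heterozygosity
#' p >= 0.5. Boundary conventions (strict for MAF/missingness, inclusive for
#' the probability filters) mirror the printed operators of those rules. An
#' upper ExcHet bound of 1.5 would be vacuous for a probability and is not a
#' parameter.
#'
#' @param maf_min,maf_max open MAF interval for relatedness/PCA sites
#' @param max_missing strict per-variant missing-fraction bound
#' @param ld_window LD-pruning window in basepairs
#' @param ld_r2_max strict squared-correlation bound for pruning
#' @param hwe_p_min inclusive lower bound on the exact HWE p-value
#' @param f_missing_max inclusive per-variant missing-fraction bound
#'   (pre-phasing filter)
#' @param exchet_p_min inclusive lower bound on the exact ExcHet p-value
#' @export
qc_thresholds <- function(maf_min = 0.05, maf_max = 0.95,
                          max_missing = 0.001,
                          ld_window = 500000, ld_r2_max = 0.1,
                          hwe_p_min = 1e-30, f_missing_max = 0.1,
                          exchet_p_min = 0.5) {
  stopifnot(maf_min >= 0, maf_min < maf_max, maf_max <= 1,
            max_missing >= 0, max_missing <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1,
            f_missing_max >= 0, f_missing_max <= 1,
            exchet_p_min >= 0, exchet_p_min <= 1,
            ld_window > 0, ld_r2_max > 0)
  structure(list(maf_min = maf_min, maf_max = maf_max,
                 max_missing = max_missing, ld_window = ld_window,
                 ld_r2_max = ld_r2_max, hwe_p_min = hwe_p_min,
                 f_missing_max = f_missing_max,
                 exchet_p_min = exchet_p_min),
            class = "qc_thresholds")
}

#' Variant filtering in three modes
#'
#' * `relatedness_pca`: keep biallelic SNVs with `maf_min < MAF < maf_max`
#'   (on the alternate-allele frequency, so both bounds bite) and missing
#'   fraction `< max_missing`.
#' * `phasing_prep`: keep variants with exact HWE p `>= hwe_p_min`, missing
#'   fraction `<= f_missing_max` and ExcHet p `>= exchet_p_min`.
#' * `monomorphic_only`: drop variants with AC = 0 or AC = AN.
#'
#' Rules are applied (and counted) in the order listed; the report records
#' how many variants each rule removed from what survived the previous ones.
#' The operation is idempotent.
#'
#' @param ds genotype_dataset
#' @param thresholds qc_thresholds
#' @param mode one of "relatedness_pca", "phasing_prep", "monomorphic_only"
#' @return list of class `qc_filter_result`: `dataset` (filtered) and
#'   `report` (data.frame rule / removed / remaining)
#' @export
filter_variants <- function(ds, thresholds = qc_thresholds(),
                            mode = c("relatedness_pca", "phasing_prep",
                                     "monomorphic_only")) {
  mode <- match.arg(mode)
  if (nrow(ds$variants) == 0) stop("empty dataset")
  th <- thresholds
  keep <- rep(TRUE, nrow(ds$variants))
  report <- data.frame(rule = character(), removed = integer(),
                       remaining = integer(), stringsAsFactors = FALSE)
  apply_rule <- function(name, pass) {
    removed <- sum(keep & !pass)
    keep <<- keep & pass
    report <<- rbind(report, data.frame(rule = name, removed = removed,
                                        remaining = sum(keep)))
  }
  an <- ds$variants$allele_number
  af <- ifelse(an > 0, ds$variants$allele_count / an, NA_real_)
  fmiss <- 1 - an / (2 * nrow(ds$samples))
  if (mode == "relatedness_pca") {
    apply_rule("snv_only", ds$variants$variant_class == "SNV")
    apply_rule("maf_open_interval",
               !is.na(af) & af > th$maf_min & af < th$maf_max)
    apply_rule("missingness", fmiss < th$max_missing)
  } else if (mode == "phasing_prep") {
    hw <- hwe_test_dataset(ds)
    apply_rule("hwe", !is.na(hw$hwe_p) & hw$hwe_p >= th$hwe_p_min)
    apply_rule("f_missing", fmiss <= th$f_missing_max)
    apply_rule("exchet", !is.na(hw$exchet_p) & hw$exchet_p >= th$exchet_p_min)
  } else {
    apply_rule("monomorphic",
               an > 0 & ds$variants$allele_count > 0 &
                 ds$variants$allele_count < an)
  }
  if (!any(keep)) warning("all variants removed by ", mode, " filtering")
  structure(list(dataset = subset_dataset(ds, variant_idx = keep),
                 report = report, mode = mode),
            class = "qc_filter_result")
}

#' @export
print.qc_filter_result <- function(x, ...) {
  cat("variant filter (", x$mode, "):\n", sep = "")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Greedy windowed LD pruning
#'
#' Left-to-right scan in position order (ties broken by ref then alt
#' lexicographically): a variant is retained iff its squared Pearson
#' correlation of dosages (missing entries dropped pairwise) with every
#' already-retained variant within `window` basepairs on the same contig is
#' below `r2_max`. Zero-variance variants cannot be in LD and are retained
#' with a message. Deterministic by construction.
#'
#' @param ds genotype_dataset
#' @param window window size in basepairs
#' @param r2_max strict r-squared threshold
#' @return sorted integer indices (into `ds$variants`) of retained variants
#' @export
ld_prune <- function(ds, window = 500000, r2_max = 0.1) {
  v <- ds$variants
  ord <- order(v$contig, v$pos, v$ref, v$alt)
  d <- ds$dosages
  sds <- apply(d, 1, stats::sd, na.rm = TRUE)
  n_zerovar <- sum(!is.na(sds) & sds == 0)
  if (n_zerovar > 0) {
    message(n_zerovar,
            " zero-variance variants treated as r2 = 0 (retained)")
  }
  retained <- integer(0)
  ret_contig <- character(0)
  ret_pos <- integer(0)
  for (i in ord) {
    ok <- TRUE
    if (length(retained) > 0 && !is.na(sds[i]) && sds[i] > 0) {
      near <- retained[ret_contig == v$contig[i] &
                         abs(ret_pos - v$pos[i]) <= window]
      near <- near[!is.na(sds[near]) & sds[near] > 0]
      if (length(near) > 0) {
        r <- suppressWarnings(
          stats::cor(d[i, ], t(d[near, , drop = FALSE]),
                     use = "pairwise.complete.obs"))
        if (any(!is.na(r) & r * r >= r2_max)) ok <- FALSE
      }
    }
    if (ok) {
      retained <- c(retained, i)
      ret_contig <- c(ret_contig, v$contig[i])
      ret_pos <- c(ret_pos, v$pos[i])
    }
  }
  sort(retained)
}

#' Per-sample QC statistics
#'
#' Counts per sample of non-reference SNV and indel genotypes, heterozygous
#' and homozygous-alternate genotypes, call rate, singletons (variants whose
#' cohort AC is exactly 1, carried as a het by this sample) and private
#' homozygotes (cohort AC = 2 carried entirely as one hom-alt genotype).
#'
#' @param ds genotype_dataset
#' @return data.frame, one row per sample
#' @export
sample_stats <- function(ds) {
  d <- ds$dosages
  snv <- ds$variants$variant_class == "SNV"
  ac <- ds$variants$allele_count
  nonref <- !is.na(d) & d > 0
  stats_df <- data.frame(
    sample_id = ds$samples$sample_id,
    population = ds$samples$population,
    region = ds$samples$region,
    n_snv = colSums(nonref[snv, , drop = FALSE]),
    n_indel = colSums(nonref[!snv, , drop = FALSE]),
    n_het = colSums(!is.na(d) & d == 1L),
    n_hom_var = colSums(!is.na(d) & d == 2L),
    n_singleton = colSums(!is.na(d[ac == 1L, , drop = FALSE]) &
                            d[ac == 1L, , drop = FALSE] == 1L),
    n_private_hom = colSums(!is.na(d[ac == 2L, , drop = FALSE]) &
                              d[ac == 2L, , drop = FALSE] == 2L),
    call_rate = colMeans(!is.na(d)),
    stringsAsFactors = FALSE
  )
  rownames(stats_df) <- NULL
  stats_df
}

#' Per-group summary of a metric
#'
#' @param stats data.frame (e.g. from [sample_stats()])
#' @param metric column name to summarize
#' @param group_by grouping column, typically "population" or "region"
#' @return data.frame with group, n, mean, sd (NA for singleton groups),
#'   min, max
#' @export
group_summary <- function(stats, metric, group_by = "population") {
  if (!metric %in% names(stats)) stop("unknown metric column: ", metric)
  if (!group_by %in% names(stats)) stop("unknown grouping column: ", group_by)
  sp <- split(stats[[metric]], stats[[group_by]])
  out <- data.frame(
    group = names(sp),
    n = vapply(sp, length, 1L),
    mean = vapply(sp, mean, 1, na.rm = TRUE),
    sd = vapply(sp, function(x) if (length(x) < 2) NA_real_ else stats::sd(x), 1),
    min = vapply(sp, min, 1, na.rm = TRUE),
    max = vapply(sp, max, 1, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Singleton counts after downsampling to equal numbers of unrelateds
#'
#' Cohort-size differences distort singleton comparisons, so each population
#' is downsampled to `n_per_pop` unrelated individuals (uniformly, seeded),
#' monomorphic variants are removed within the combined subset, and
#' singletons are counted per individual; the per-population mean is
#' reported. Populations with fewer than `n_per_pop` unrelated samples are
#' skipped with a warning.
#'
#' @param ds genotype_dataset
#' @param unrelated_ids sample ids considered unrelated
#' @param n_per_pop samples retained per population (default 4)
#' @param seed integer seed
#' @return list: `per_sample` stats on the subset, `per_population` mean
#'   singleton table, `skipped` population labels
#' @export
downsample_singletons <- function(ds, unrelated_ids, n_per_pop = 4, seed = 1) {
  set.seed(seed)
  s <- ds$samples
  pools <- split(intersect(unrelated_ids, s$sample_id),
                 s$population[match(intersect(unrelated_ids, s$sample_id),
                                    s$sample_id)])
  skipped <- names(pools)[lengths(pools) < n_per_pop]
  if (length(skipped) > 0) {
    warning("populations with fewer than ", n_per_pop,
            " unrelated samples skipped: ", paste(skipped, collapse = ", "))
  }
  pools <- pools[lengths(pools) >= n_per_pop]
  if (length(pools) == 0) stop("no population has enough unrelated samples")
  chosen <- unlist(lapply(pools, function(ids)
    sort(sample(ids, n_per_pop))), use.names = FALSE)
  sub <- subset_dataset(ds, sample_ids = chosen)
  sub <- filter_variants(sub, mode = "monomorphic_only")$dataset
  st <- sample_stats(sub)
  per_pop <- group_summary(st, "n_singleton", "population")
  list(per_sample = st, per_population = per_pop, skipped = skipped)
}
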