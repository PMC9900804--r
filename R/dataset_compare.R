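#' Subtract a nested cohort's allele counts ("synthetic complement" cohort)
#'
#' Given per-variant AC/AN for a full callset and for a nested subset of its
#' samples, exact integer subtraction yields the counts the remaining
#' samples contribute - a synthetic version of the complement cohort without
#' touching genotypes. Variants whose complement is monomorphic
#' (synth AC = 0 or synth AC = synth AN) are flagged.
#'
#' @param full data.frame with columns `key`, `ac`, `an` for the full cohort
#' @param subset data.frame with the same columns for the nested cohort;
#'   keys absent from `subset` are treated as AC = AN = 0 contributions
#' @return data.frame: key, ac, an, maf, monomorphic
#' @export
subtract_counts <- function(full, subset) {
  stopifnot(all(c("key", "ac", "an") %in% names(full)),
            all(c("key", "ac", "an") %in% names(subset)))
  if (anyDuplicated(full$key)) stop("duplicate keys in full table")
  if (anyDuplicated(subset$key)) stop("duplicate keys in subset table")
  idx <- match(full$key, subset$key)
  sub_ac <- ifelse(is.na(idx), 0L, subset$ac[idx])
  sub_an <- ifelse(is.na(idx), 0L, subset$an[idx])
  bad <- which(sub_ac > full$ac | sub_an > full$an)
  if (length(bad) > 0) {
    stop("subset counts exceed full counts at: ",
         paste(utils::head(full$key[bad], 5), collapse = ", "))
  }
  ac <- full$ac - sub_ac
  an <- full$an - sub_an
  af <- ifelse(an > 0, ac / an, NA_real_)
  data.frame(key = full$key, ac = ac, an = an,
             maf = pmin(af, 1 - af),
             monomorphic = an == 0L | ac == 0L | ac == an,
             stringsAsFactors = FALSE)
}

#' Overlap flags between two variant key sets
#'
#' @param reference_keys,comparison_keys canonical post-split variant keys
#' @return list: `in_comparison` (logical per reference key),
#'   `in_reference` (logical per comparison key), and counts
#'   (`n_shared`, `n_reference_only`, `n_comparison_only`)
#' @export
overlap_flags <- function(reference_keys, comparison_keys) {
  for (nm in c("reference", "comparison")) {
    keys <- if (nm == "reference") reference_keys else comparison_keys
    dup <- unique(keys[duplicated(keys)])
    if (length(dup) > 0) {
      stop("duplicate keys in ", nm, " set: ",
           paste(utils::head(dup, 5), collapse = ", "))
    }
  }
  in_comp <- reference_keys %in% comparison_keys
  in_ref <- comparison_keys %in% reference_keys
  list(in_comparison = in_comp, in_reference = in_ref,
       n_shared = sum(in_comp),
       n_reference_only = sum(!in_comp),
       n_comparison_only = sum(!in_ref))
}

#' MAF-binned shared/unique partition of two callsets
#'
#' Reference variants are binned by their reference MAF and split into
#' `shared` versus `reference_only` by presence in the comparison set;
#' variants present only in the comparison set are counted into a special
#' `0%` bin (their frequency in the reference is zero by absence). Margins
#' are conserved: shared + reference_only sums to the binned reference
#' variants, and the grand total is reference + comparison-only.
#'
#' @param reference data.frame with `key`, `ac`, `an` (or a
#'   genotype_dataset)
#' @param comparison same as `reference`
#' @param bin_edges increasing MAF bin edges within (0, 0.5]
#'   (default 0.001, 0.01, 0.05, 0.5); bins are (0, e1], (e1, e2], ...
#' @return object of class `maf_bin_table`: data.frame with bin, shared,
#'   reference_only, comparison_only columns; excluded AN = 0 variants are
#'   reported in the `n_excluded` attribute
#' @export
maf_bin_comparison <- function(reference, comparison,
                               bin_edges = c(0.001, 0.01, 0.05, 0.5)) {
  as_table <- function(x) {
    if (inherits(x, "genotype_dataset")) {
      data.frame(key = variant_keys(x), ac = x$variants$allele_count,
                 an = x$variants$allele_number, stringsAsFactors = FALSE)
    } else x
  }
  reference <- as_table(reference); comparison <- as_table(comparison)
  if (any(diff(bin_edges) <= 0) || any(bin_edges <= 0) ||
      any(bin_edges > 0.5)) {
    stop("bin_edges must be strictly increasing within (0, 0.5]")
  }
  fl <- overlap_flags(reference$key, comparison$key)
  excluded <- reference$an == 0L
  if (any(excluded)) {
    message("excluding ", sum(excluded), " reference variants with AN = 0")
  }
  ref <- reference[!excluded, , drop = FALSE]
  in_comp <- fl$in_comparison[!excluded]
  af <- ref$ac / ref$an
  maf <- pmin(af, 1 - af)
  # monomorphic reference records (MAF exactly 0) stay in the lowest bin so
  # the margins remain a partition of the reference set
  maf[maf == 0] <- .Machine$double.xmin
  brks <- c(0, bin_edges)
  bin <- cut(maf, brks, include.lowest = FALSE)
  labels <- levels(bin)
  tab <- data.frame(
    bin = c("0% (comparison-only)", labels),
    shared = c(0L, as.integer(table(bin[in_comp]))),
    reference_only = c(0L, as.integer(table(bin[!in_comp]))),
    comparison_only = c(fl$n_comparison_only, rep(0L, length(labels))),
    stringsAsFactors = FALSE
  )
  tab$total <- tab$shared + tab$reference_only + tab$comparison_only
  structure(tab, n_excluded = sum(excluded), class = c("maf_bin_table",
                                                       "data.frame"))
}

#' Pre/post-QC exclusive-variant grid
#'
#' For every combination of reference QC state and comparison QC state,
#' counts the comparison variants absent from the reference, split by
#' variant class - the bookkeeping used to ask whether QC explains variants
#' missing from a harmonized callset.
#'
#' @param reference_pre,reference_post,comparison_pre,comparison_post
#'   data.frames with columns `key` and `variant_class`
#' @return data.frame: reference_state, comparison_state, n_snv_exclusive,
#'   n_indel_exclusive, n_exclusive
#' @export
qc_overlap_grid <- function(reference_pre, reference_post,
                            comparison_pre, comparison_post) {
  refs <- list(pre = reference_pre, post = reference_post)
  comps <- list(pre = comparison_pre, post = comparison_post)
  rows <- list()
  for (rs in names(refs)) {
    for (cs in names(comps)) {
      comp <- comps[[cs]]
      excl <- !(comp$key %in% refs[[rs]]$key)
      rows[[paste(rs, cs)]] <- data.frame(
        reference_state = rs, comparison_state = cs,
        n_snv_exclusive = sum(excl & comp$variant_class == "SNV"),
        n_indel_exclusive = sum(excl & comp$variant_class == "indel"),
        n_exclusive = sum(excl), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
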