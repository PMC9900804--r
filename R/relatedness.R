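#' KING-robust pairwise kinship
#'
#' Moment estimator of the kinship coefficient phi from identity-by-state
#' counts, computed over sites called in both samples:
#' phi_ij = (N_AaAa - 2 N_AAaa) / (N_Aa(i) + N_Aa(j)),
#' where N_AaAa counts sites heterozygous in both, N_AAaa sites with opposite
#' homozygotes, and N_Aa(s) the heterozygous sites of sample s among the
#' shared-called sites. Robust to population structure because it never uses
#' cohort allele frequencies; 0.5 for duplicates, ~0.25 for parent-offspring,
#' ~0 for unrelated pairs, negative for structurally diverged pairs. The
#' estimator is invariant to ref/alt relabeling at any site. Implemented with
#' indicator-matrix cross-products, so the full pairwise table on tens of
#' thousands of sites takes seconds.
#'
#' Input should be the `relatedness_pca` QC output (common biallelic SNVs,
#' near-complete calls), LD-pruned when sites are correlated.
#'
#' @param ds genotype_dataset with at least two samples
#' @return object of class `kinship_table`: data.frame with columns
#'   `i`, `j` (sample ids, i < j in input order), `phi`, `n_shared`
#'   (shared-called sites); pairs with no heterozygous sites in either
#'   sample get `phi = NA`. Classification thresholds are attached as the
#'   `thresholds` attribute.
#' @export
king_kinship <- function(ds) {
  d <- ds$dosages
  n <- ncol(d)
  if (n < 2) stop("kinship requires at least two samples")
  het <- (!is.na(d) & d == 1L) * 1
  homr <- (!is.na(d) & d == 0L) * 1
  homa <- (!is.na(d) & d == 2L) * 1
  called <- (!is.na(d)) * 1
  n_aa_aa <- crossprod(het)                    # both het
  n_opp <- crossprod(homr, homa)               # i hom-ref, j hom-alt
  n_opp <- n_opp + t(n_opp)                    # opposite homozygotes
  het_on_shared <- crossprod(het, called)      # N_Aa(i) over sites called in j
  denom <- het_on_shared + t(het_on_shared)
  n_shared <- crossprod(called)
  phi <- (n_aa_aa - 2 * n_opp) / denom
  ut <- which(upper.tri(phi), arr.ind = TRUE)
  ids <- ds$samples$sample_id
  kt <- data.frame(
    i = ids[ut[, 1]], j = ids[ut[, 2]],
    phi = ifelse(denom[ut] > 0, phi[ut], NA_real_),
    n_shared = as.integer(n_shared[ut]),
    stringsAsFactors = FALSE
  )
  structure(kt,
            thresholds = list(unrelated_max = 0.05, po_low = 0.248,
                              po_high = 0.252, dup_min = 0.35),
            class = c("kinship_table", "data.frame"))
}

#' Look up kinship for given pairs
#' @param kt kinship_table
#' @param a,b sample id vectors (pairs are unordered)
#' @return numeric phi per pair (NA when the pair is absent)
#' @export
kinship_lookup <- function(kt, a, b) {
  key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  kt_key <- key(kt$i, kt$j)
  kt$phi[match(key(a, b), kt_key)]
}

#' Maximal independent set of unrelated samples
#'
#' Builds the relatedness graph with an edge for every pair with
#' `phi > threshold`, then iteratively removes the highest-degree vertex
#' (ties broken by lexicographic sample id) until no edge remains. Removed
#' vertices that end up with no retained neighbour are added back, so the
#' result is a maximal independent set: no retained pair is related, and no
#' excluded sample could be added without violating that. Deterministic for
#' a given input.
#'
#' @param kt kinship_table
#' @param threshold kinship bound above which a pair counts as related
#'   (default 0.05)
#' @return list of class `relatedness_partition`: `unrelated_ids`,
#'   `related_ids`, `threshold`
#' @export
unrelated_set <- function(kt, threshold = 0.05) {
  all_ids <- sort(unique(c(kt$i, kt$j)))
  rel <- kt[!is.na(kt$phi) & kt$phi > threshold, c("i", "j")]
  adj <- new.env(parent = emptyenv())
  for (id in all_ids) assign(id, character(0), envir = adj)
  for (r in seq_len(nrow(rel))) {
    assign(rel$i[r], c(get(rel$i[r], envir = adj), rel$j[r]), envir = adj)
    assign(rel$j[r], c(get(rel$j[r], envir = adj), rel$i[r]), envir = adj)
  }
  active <- stats::setNames(rep(TRUE, length(all_ids)), all_ids)
  removed <- character(0)
  while (TRUE) {
    cur_deg <- vapply(names(active)[active], function(id)
      sum(active[get(id, envir = adj)]), 1L)
    if (length(cur_deg) == 0 || max(cur_deg) == 0) break
    worst <- names(cur_deg)[cur_deg == max(cur_deg)]
    drop_id <- sort(worst)[1]
    active[drop_id] <- FALSE
    removed <- c(removed, drop_id)
  }
  # maximality pass: re-admit removed vertices with no retained neighbour
  for (id in sort(removed)) {
    if (!any(active[get(id, envir = adj)])) active[id] <- TRUE
  }
  structure(list(unrelated_ids = names(active)[active],
                 related_ids = names(active)[!active],
                 threshold = threshold),
            class = "relatedness_partition")
}

#' @export
print.relatedness_partition <- function(x, ...) {
  cat("relatedness partition (phi >", x$threshold, "related):",
      length(x$unrelated_ids), "unrelated /",
      length(x$related_ids), "related\n")
  invisible(x)
}

#' Classify sample pairs by kinship
#'
#' Screening tiers used for pedigree and duplicate checks:
#' `duplicate_or_MZ` for phi > 0.35, `parent_offspring_window` for
#' phi in \[0.248, 0.252\] (the screening window bracketing the theoretical
#' 0.25), `unrelated` for phi <= 0.05, `other_related` otherwise. Pairs with
#' undefined phi (no heterozygotes in either sample) are labelled NA.
#'
#' @param kt kinship_table
#' @return the table with a `label` column appended
#' @export
classify_pairs <- function(kt) {
  th <- attr(kt, "thresholds")
  if (is.null(th)) th <- list(unrelated_max = 0.05, po_low = 0.248,
                              po_high = 0.252, dup_min = 0.35)
  phi <- kt$phi
  label <- rep(NA_character_, length(phi))
  ok <- !is.na(phi)
  label[ok & phi > th$dup_min] <- "duplicate_or_MZ"
  label[ok & phi >= th$po_low & phi <= th$po_high] <- "parent_offspring_window"
  label[ok & is.na(label) & phi <= th$unrelated_max] <- "unrelated"
  label[ok & is.na(label)] <- "other_related"
  kt$label <- label
  kt
}

#' Planted relationship pairs from pedigree metadata
#'
#' Reads `mother_id` / `father_id` / `duplicate_of` from the sample table
#' and returns the known related pairs, the ground truth for kinship
#' evaluations on simulated cohorts.
#'
#' @param ds genotype_dataset (or a samples data.frame)
#' @return data.frame: i, j, relationship ("parent_offspring" or
#'   "duplicate")
#' @export
pedigree_pairs <- function(ds) {
  s <- if (inherits(ds, "genotype_dataset")) ds$samples else ds
  rows <- list()
  add <- function(a, b, rel) {
    ok <- !is.na(a) & a %in% s$sample_id
    if (any(ok)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        i = pmin(a[ok], b[ok]), j = pmax(a[ok], b[ok]),
        relationship = rel, stringsAsFactors = FALSE)
    }
  }
  add(s$mother_id, s$sample_id, "parent_offspring")
  add(s$father_id, s$sample_id, "parent_offspring")
  add(s$duplicate_of, s$sample_id, "duplicate")
  if (length(rows) == 0) {
    return(data.frame(i = character(), j = character(),
                      relationship = character(), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Identity-by-state sharing for one sample pair
#'
#' @param ds genotype_dataset
#' @param sample_i,sample_j sample ids
#' @return list with `ibs0`, `ibs1`, `ibs2` counts over shared-called sites
#' @export
ibs_sharing <- function(ds, sample_i, sample_j) {
  ii <- match(sample_i, ds$samples$sample_id)
  jj <- match(sample_j, ds$samples$sample_id)
  if (is.na(ii) || is.na(jj)) stop("unknown sample id")
  gi <- ds$dosages[, ii]; gj <- ds$dosages[, jj]
  ok <- !is.na(gi) & !is.na(gj)
  diff <- abs(gi[ok] - gj[ok])
  list(ibs0 = sum(diff == 2L), ibs1 = sum(diff == 1L), ibs2 = sum(diff == 0L))
}
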