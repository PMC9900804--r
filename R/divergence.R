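#' Pairwise Weir-Cockerham F_ST between populations
#'
#' For each population pair, the Weir & Cockerham (1984) theta-hat is
#' computed per biallelic variant from the two populations' called sample
#' sizes, allele frequencies and observed heterozygote frequencies, and
#' combined across variants as a ratio of averages (sum of the
#' among-population variance components over the sum of total components).
#' Variants monomorphic across the pair are skipped. A Hudson-style
#' estimator (mean of (1 - Hw/Hb) components, also ratio-of-averages) is
#' available for sensitivity checks.
#'
#' @param ds genotype_dataset
#' @param maf_min pooled-pair MAF must exceed this for a variant to enter
#'   (default 0.05, the common-variant convention; set 0 to use every
#'   polymorphic site)
#' @param estimator "wc" (default) or "hudson"
#' @return object of class `fst_matrix`: `populations`, `values` (symmetric
#'   matrix, zero diagonal), `n_variants` (matrix of sites used per pair)
#' @export
fst_pairwise <- function(ds, maf_min = 0.05, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  pops <- sort(unique(ds$samples$population))
  if (length(pops) < 2) stop("need at least two populations")
  sizes <- table(ds$samples$population)
  if (any(sizes < 2)) {
    stop("populations with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  d <- ds$dosages
  # per-population called counts, allele counts, het counts per variant
  stats_by_pop <- lapply(pops, function(pp) {
    cols <- ds$samples$population == pp
    dp <- d[, cols, drop = FALSE]
    called <- !is.na(dp)
    list(n = rowSums(called),
         ac = rowSums(dp, na.rm = TRUE),
         nhet = rowSums(!is.na(dp) & dp == 1L))
  })
  names(stats_by_pop) <- pops
  np <- length(pops)
  values <- matrix(0, np, np, dimnames = list(pops, pops))
  nv_used <- matrix(0L, np, np, dimnames = list(pops, pops))
  for (a in seq_len(np - 1)) {
    for (b in (a + 1):np) {
      s1 <- stats_by_pop[[a]]; s2 <- stats_by_pop[[b]]
      ok <- s1$n >= 2 & s2$n >= 2
      p1 <- s1$ac / (2 * s1$n); p2 <- s2$ac / (2 * s2$n)
      pbar_all <- (s1$ac + s2$ac) / (2 * (s1$n + s2$n))
      poly <- ok & pbar_all > 0 & pbar_all < 1
      if (maf_min > 0) poly <- poly & pmin(pbar_all, 1 - pbar_all) > maf_min
      if (!any(poly)) {
        values[a, b] <- values[b, a] <- NA_real_
        next
      }
      n1 <- s1$n[poly]; n2 <- s2$n[poly]
      f1 <- p1[poly]; f2 <- p2[poly]
      h1 <- s1$nhet[poly] / n1; h2 <- s2$nhet[poly] / n2
      est <- if (estimator == "wc") {
        wc_theta_components(n1, n2, f1, f2, h1, h2)
      } else {
        hudson_components(n1, n2, f1, f2)
      }
      values[a, b] <- values[b, a] <- sum(est$num) / sum(est$den)
      nv_used[a, b] <- nv_used[b, a] <- sum(poly)
    }
  }
  structure(list(populations = pops, values = values, n_variants = nv_used,
                 estimator = estimator, maf_min = maf_min),
            class = "fst_matrix")
}

# Weir & Cockerham (1984) variance components for r = 2 populations,
# one biallelic variant, vectorized over variants.
wc_theta_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(num = a, den = a + b + cc)
}

# Hudson estimator components: numerator Hb - Hw, denominator Hb,
# with unbiased within-population heterozygosity.
hudson_components <- function(n1, n2, p1, p2) {
  hw <- (n1 / (n1 - 1) * 2 * p1 * (1 - p1) +
           n2 / (n2 - 1) * 2 * p2 * (1 - p2)) / 2
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = hb - hw, den = hb)
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("pairwise F_ST (", x$estimator, ", pooled MAF > ", x$maf_min, "):\n",
      sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Cluster populations by pairwise F_ST
#'
#' Average-linkage hierarchical clustering treating the F_ST matrix as a
#' dissimilarity (tiny negative estimates are clamped to zero). Leaf order
#' and merge heights are returned; label order in the input does not change
#' merge heights.
#'
#' @param fst fst_matrix
#' @return list: `order` (leaf labels), `heights`, `hclust`
#' @export
cluster_populations <- function(fst) {
  m <- fst$values
  if (any(is.na(m))) {
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    stop("NA F_ST entries for pairs: ",
         paste(paste(rownames(m)[bad[, 1]], colnames(m)[bad[, 2]], sep = "-"),
               collapse = ", "))
  }
  m <- pmax(m, 0)
  # canonical label order makes tie-breaking deterministic
  ord <- order(rownames(m))
  hc <- stats::hclust(stats::as.dist(m[ord, ord]), method = "average")
  list(order = hc$labels[hc$order], heights = hc$height, hclust = hc)
}

#' Pairwise doubleton sharing (f2 analysis)
#'
#' A doubleton is a variant whose alternate allele appears exactly twice in
#' the chosen sample scope. When the two copies sit in two distinct
#' individuals (both heterozygous), that pair shares the doubleton and its
#' cell in the sample-by-sample count matrix is incremented; when one
#' individual carries both copies (homozygous alternate) it is tallied as a
#' private homozygote instead, since sharing requires two individuals.
#' Summaries (mean count for within-population pairs, cross-population
#' pairs within a region, and cross-region pairs) are computed from the
#' matrix and the sample metadata.
#'
#' @param ds genotype_dataset
#' @param scope "all" (default) or "unrelated"
#' @param unrelated_ids required when `scope = "unrelated"`
#' @return object of class `doubleton_matrix`: `samples`, `counts`
#'   (symmetric integer matrix), `private_hom_counts`, `summary`
#' @export
count_doubletons <- function(ds, scope = c("all", "unrelated"),
                             unrelated_ids = NULL) {
  scope <- match.arg(scope)
  if (scope == "unrelated") {
    if (is.null(unrelated_ids)) stop("unrelated scope requires unrelated_ids")
    ds <- subset_dataset(ds, sample_ids = intersect(unrelated_ids,
                                                    ds$samples$sample_id))
  }
  d <- ds$dosages
  ids <- ds$samples$sample_id
  n <- length(ids)
  ac <- rowSums(d, na.rm = TRUE)
  counts <- matrix(0L, n, n, dimnames = list(ids, ids))
  private_hom <- stats::setNames(integer(n), ids)
  for (v in which(ac == 2L)) {
    g <- d[v, ]
    hom <- which(!is.na(g) & g == 2L)
    if (length(hom) == 1L) {
      private_hom[hom] <- private_hom[hom] + 1L
    } else {
      het <- which(!is.na(g) & g == 1L)
      if (length(het) == 2L) {
        counts[het[1], het[2]] <- counts[het[1], het[2]] + 1L
        counts[het[2], het[1]] <- counts[het[2], het[1]] + 1L
      }
    }
  }
  pop <- ds$samples$population
  reg <- ds$samples$region
  ut <- which(upper.tri(counts), arr.ind = TRUE)
  same_pop <- pop[ut[, 1]] == pop[ut[, 2]]
  same_reg <- reg[ut[, 1]] == reg[ut[, 2]]
  vals <- counts[ut]
  summ <- data.frame(
    pair_type = c("within_population", "cross_population_within_region",
                  "cross_region"),
    n_pairs = c(sum(same_pop), sum(!same_pop & same_reg), sum(!same_reg)),
    mean_doubletons = c(mean(vals[same_pop]),
                        mean(vals[!same_pop & same_reg]),
                        mean(vals[!same_reg]))
  )
  structure(list(samples = ids, counts = counts,
                 private_hom_counts = private_hom, summary = summ,
                 scope = scope),
            class = "doubleton_matrix")
}

#' @export
print.doubleton_matrix <- function(x, ...) {
  cat("doubleton sharing over", length(x$samples), "samples (scope:",
      x$scope, ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
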