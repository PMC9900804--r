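#' Genotype dataset container
#'
#' The central data structure of popkit: a variants-by-samples dosage matrix
#' with variant and sample metadata. Dosages count copies of the single
#' alternate allele (0, 1, 2) with `NA` marking missing genotypes; missing
#' entries contribute to neither the allele count (AC) nor the allele number
#' (AN). Optionally carries phased haplotypes as two parallel 0/1 matrices
#' whose sum equals the dosage matrix wherever the genotype is called.
#'
#' @param variants data.frame with columns `contig`, `pos`, `ref`, `alt`
#'   (one alternate allele per record); `allele_count`, `allele_number`,
#'   `variant_class` and `filters` are recomputed/filled if absent.
#' @param samples data.frame with column `sample_id` (unique); optional
#'   columns `population`, `region`, `project`, `latitude`, `longitude`,
#'   `mother_id`, `father_id`, `mean_coverage`, `duplicate_of`.
#' @param dosages integer matrix, `nrow(variants)` x `nrow(samples)`,
#'   entries in `{0, 1, 2, NA}`.
#' @param hap1,hap2 optional 0/1 haplotype matrices (same shape as
#'   `dosages`); required when `phased = TRUE`.
#' @param phased logical; whether haplotypes carry phase information.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(variants, samples, dosages,
                             hap1 = NULL, hap2 = NULL, phased = FALSE) {
  variants <- as.data.frame(variants)
  samples <- as.data.frame(samples)
  stopifnot(is.matrix(dosages))
  if (nrow(variants) != nrow(dosages) || nrow(samples) != ncol(dosages)) {
    stop("dosage matrix dimensions (", nrow(dosages), " x ", ncol(dosages),
         ") do not match metadata (", nrow(variants), " variants, ",
         nrow(samples), " samples)")
  }
  req <- c("contig", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0) stop("variants table lacks columns: ",
                             paste(miss, collapse = ", "))
  if (!"sample_id" %in% names(samples)) stop("samples table lacks sample_id")
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  if (any(variants$pos < 1)) stop("variant pos must be >= 1 (VCF convention)")
  bad <- dosages[!is.na(dosages) & !(dosages %in% 0:2)]
  if (length(bad) > 0) stop("dosages must be in {0, 1, 2, NA}")
  for (col in c("population", "region", "project")) {
    if (!col %in% names(samples)) samples[[col]] <- NA_character_
  }
  for (col in c("latitude", "longitude", "mean_coverage")) {
    if (!col %in% names(samples)) samples[[col]] <- NA_real_
  }
  for (col in c("mother_id", "father_id", "duplicate_of")) {
    if (!col %in% names(samples)) samples[[col]] <- NA_character_
  }
  lat <- samples$latitude
  lon <- samples$longitude
  if (any(!is.na(lat) & (lat < -90 | lat > 90))) stop("latitude outside [-90, 90]")
  if (any(!is.na(lon) & (lon <= -180 | lon > 180))) stop("longitude outside (-180, 180]")
  for (col in c("mother_id", "father_id")) {
    ids <- samples[[col]]
    unknown <- setdiff(ids[!is.na(ids) & ids != "" & ids != "0"],
                       samples$sample_id)
    if (length(unknown) > 0) {
      stop(col, " refers to unknown samples: ", paste(unknown, collapse = ", "))
    }
  }
  if (!"filters" %in% names(variants)) variants$filters <- "PASS"
  if (!"variant_class" %in% names(variants)) {
    variants$variant_class <- classify_variant(variants$ref, variants$alt)
  }
  if (phased) {
    if (is.null(hap1) || is.null(hap2)) stop("phased dataset requires hap1 and hap2")
    stopifnot(identical(dim(hap1), dim(dosages)),
              identical(dim(hap2), dim(dosages)))
    hsum <- hap1 + hap2
    ok <- is.na(dosages) | (!is.na(hsum) & hsum == dosages)
    if (!all(ok)) stop("haplotype allele sums disagree with dosages at ",
                       sum(!ok), " entries")
  }
  dimnames(dosages) <- list(NULL, samples$sample_id)
  if (!is.null(hap1)) dimnames(hap1) <- dimnames(dosages)
  if (!is.null(hap2)) dimnames(hap2) <- dimnames(dosages)
  ds <- structure(list(variants = variants, samples = samples,
                       dosages = dosages, hap1 = hap1, hap2 = hap2,
                       phased = isTRUE(phased)),
                  class = "genotype_dataset")
  recompute_allele_counts(ds)
}

#' Recompute AC/AN from the dosage matrix
#'
#' Missing genotypes reduce AN by two; AC is the sum of called dosages.
#' Every operation that changes samples or genotypes calls this, so stored
#' counts always match a brute-force recount.
#'
#' @param ds genotype_dataset
#' @return the dataset with `allele_count` / `allele_number` refreshed.
#' @export
recompute_allele_counts <- function(ds) {
  called <- !is.na(ds$dosages)
  ds$variants$allele_number <- as.integer(2L * rowSums(called))
  ds$variants$allele_count <- as.integer(rowSums(ds$dosages, na.rm = TRUE))
  ds
}

#' Variant keys (contig:pos:ref:alt)
#' @param ds genotype_dataset (or a variants data.frame)
#' @return character vector of canonical variant keys
#' @export
variant_keys <- function(ds) {
  v <- if (inherits(ds, "genotype_dataset")) ds$variants else ds
  paste(v$contig, v$pos, v$ref, v$alt, sep = ":")
}

#' Minor allele frequency per variant
#' @param ds genotype_dataset
#' @return numeric vector; NA where AN = 0
#' @export
variant_maf <- function(ds) {
  an <- ds$variants$allele_number
  af <- ifelse(an > 0, ds$variants$allele_count / an, NA_real_)
  pmin(af, 1 - af)
}

#' Alternate allele frequency per variant
#' @param ds genotype_dataset
#' @return numeric vector; NA where AN = 0
#' @export
variant_af <- function(ds) {
  an <- ds$variants$allele_number
  ifelse(an > 0, ds$variants$allele_count / an, NA_real_)
}

#' Classify variants as SNV or indel by allele length
#'
#' A record is an SNV iff both alleles are single bases; anything else
#' (insertions, deletions, MNP-style length changes) is an indel. Symbolic
#' (`<DEL>`-style) and star alleles are rejected.
#'
#' @param ref,alt character vectors of allele strings
#' @return character vector, "SNV" or "indel"
#' @export
classify_variant <- function(ref, alt) {
  if (any(ref == "" | alt == "")) stop("empty allele string")
  sym <- grepl("^<|\\*|\\[|\\]", ref) | grepl("^<|\\*|\\[|\\]", alt)
  if (any(sym)) {
    stop("symbolic or star alleles are unsupported: ",
         paste(utils::head(paste(ref[sym], alt[sym], sep = "/"), 5),
               collapse = ", "))
  }
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "indel")
}

#' Subset a genotype dataset by samples and/or variants
#'
#' @param ds genotype_dataset
#' @param sample_ids character vector of sample ids to keep (default all)
#' @param variant_idx integer or logical index over variants (default all)
#' @return genotype_dataset with AC/AN recomputed on the subset
#' @export
subset_dataset <- function(ds, sample_ids = NULL, variant_idx = NULL) {
  si <- seq_len(nrow(ds$samples))
  if (!is.null(sample_ids)) {
    si <- match(sample_ids, ds$samples$sample_id)
    if (anyNA(si)) {
      stop("unknown sample ids: ",
           paste(sample_ids[is.na(si)], collapse = ", "))
    }
  }
  vi <- seq_len(nrow(ds$variants))
  if (!is.null(variant_idx)) {
    if (is.logical(variant_idx)) {
      stopifnot(length(variant_idx) == nrow(ds$variants))
      vi <- which(variant_idx)
    } else {
      if (any(variant_idx < 1 | variant_idx > nrow(ds$variants))) {
        stop("variant index out of range")
      }
      vi <- as.integer(variant_idx)
    }
  }
  samples <- ds$samples[si, , drop = FALSE]
  # pedigree links that leave the subset are cut, not an error
  for (col in c("mother_id", "father_id", "duplicate_of")) {
    keep <- samples[[col]] %in% samples$sample_id
    samples[[col]][!keep] <- NA_character_
  }
  rownames(samples) <- NULL
  variants <- ds$variants[vi, , drop = FALSE]
  rownames(variants) <- NULL
  out <- structure(list(
    variants = variants,
    samples = samples,
    dosages = ds$dosages[vi, si, drop = FALSE],
    hap1 = if (!is.null(ds$hap1)) ds$hap1[vi, si, drop = FALSE],
    hap2 = if (!is.null(ds$hap2)) ds$hap2[vi, si, drop = FALSE],
    phased = ds$phased
  ), class = "genotype_dataset")
  recompute_allele_counts(out)
}

#' Split multi-allelic records into one record per alternate allele
#'
#' Datasets read with `read_vcf(..., split = FALSE)` may hold raw GT codes
#' for records with several alternate alleles. Each such record becomes one
#' record per alternate, with dosages recoded as copies of that alternate;
#' biallelic records pass through unchanged, so the operation is idempotent.
#'
#' @param ds genotype_dataset, possibly carrying a `gt_codes` attribute of
#'   raw GT strings with comma-separated `alt`
#' @return biallelic genotype_dataset with AC/AN recomputed
#' @export
split_multiallelic <- function(ds) {
  gt <- attr(ds, "gt_codes")
  multi <- grepl(",", ds$variants$alt, fixed = TRUE)
  if (!any(multi)) {
    attr(ds, "gt_codes") <- NULL
    return(recompute_allele_counts(ds))
  }
  if (is.null(gt)) {
    stop("multi-allelic records present but raw GT codes unavailable; ",
         "read the VCF with read_vcf() to allow splitting")
  }
  v <- ds$variants
  pieces <- strsplit(v$alt, ",", fixed = TRUE)
  n_out <- sum(lengths(pieces))
  nsamp <- nrow(ds$samples)
  dos <- matrix(NA_integer_, n_out, nsamp)
  h1 <- if (ds$phased) matrix(NA_integer_, n_out, nsamp)
  h2 <- if (ds$phased) matrix(NA_integer_, n_out, nsamp)
  out_rows <- vector("list", n_out)
  r <- 0L
  for (i in seq_len(nrow(v))) {
    alts <- pieces[[i]]
    codes <- gt[i, ]
    al <- parse_gt_codes(codes)
    for (a in seq_along(alts)) {
      r <- r + 1L
      out_rows[[r]] <- data.frame(contig = v$contig[i], pos = v$pos[i],
                                  ref = v$ref[i], alt = alts[a],
                                  filters = v$filters[i],
                                  stringsAsFactors = FALSE)
      d1 <- as.integer(al$a1 == a)
      d2 <- as.integer(al$a2 == a)
      dos[r, ] <- d1 + d2
      if (ds$phased) {
        h1[r, ] <- d1
        h2[r, ] <- d2
      }
    }
  }
  variants <- do.call(rbind, out_rows)
  variants$variant_class <- classify_variant(variants$ref, variants$alt)
  genotype_dataset(variants, ds$samples, dos, hap1 = h1, hap2 = h2,
                   phased = ds$phased)
}

# GT strings ("0/1", "1|2", "./.", ".") -> integer allele index pair (NA = missing)
parse_gt_codes <- function(codes) {
  parts <- strsplit(codes, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  a2 <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2) p[2] else NA_character_, "")))
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  list(a1 = a1, a2 = a2)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$variants), "variants x",
      nrow(x$samples), "samples\n")
  cat("  phased:", x$phased, "\n")
  ncalls <- length(x$dosages)
  cat(sprintf("  missing genotypes: %.3f%%\n",
              100 * sum(is.na(x$dosages)) / max(1, ncalls)))
  pops <- table(x$samples$population)
  if (length(pops) > 0 && !all(is.na(names(pops)))) {
    cat("  populations:", paste(names(pops), "(", pops, ")",
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.genotype_dataset <- function(object, ...) {
  maf <- variant_maf(object)
  out <- list(
    n_variants = nrow(object$variants),
    n_samples = nrow(object$samples),
    n_snv = sum(object$variants$variant_class == "SNV"),
    n_indel = sum(object$variants$variant_class == "indel"),
    missing_rate = mean(is.na(object$dosages)),
    maf_quartiles = stats::quantile(maf, c(0.25, 0.5, 0.75), na.rm = TRUE),
    phased = object$phased
  )
  class(out) <- "summary.genotype_dataset"
  out
}

#' @export
print.summary.genotype_dataset <- function(x, ...) {
  cat(x$n_variants, "variants (", x$n_snv, "SNV,", x$n_indel, "indel ) x",
      x$n_samples, "samples; phased:", x$phased, "\n")
  cat(sprintf("missing rate %.4f; MAF quartiles %.3f / %.3f / %.3f\n",
              x$missing_rate, x$maf_quartiles[1], x$maf_quartiles[2],
              x$maf_quartiles[3]))
  invisible(x)
}
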