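#' Read a VCF into a genotype_dataset
#'
#' Parses a VCF v4.2 (via vcfR) into the package's dosage representation.
#' `|`-separated genotypes populate phased haplotypes (the dataset is marked
#' phased only when every called genotype is phased); `./.` becomes a missing
#' entry that drops out of both AC and AN, which are always recomputed from
#' the genotypes rather than trusted from INFO. Multi-allelic records are
#' split into one record per alternate allele by default. Records on the X
#' or Y chromosome are rejected; star and symbolic alternate alleles are
#' dropped with a message.
#'
#' @param path VCF file (plain text or gzipped)
#' @param metadata optional sample metadata: a data.frame or TSV path with a
#'   `sample_id` column. Metadata samples absent from the VCF raise a
#'   reconciliation error; VCF samples without metadata rows get NA fields.
#' @param split split multi-allelic records (default TRUE)
#' @return genotype_dataset
#' @export
read_vcf <- function(path, metadata = NULL, split = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fixm <- vcfR::getFIX(vcf)
  if (is.null(dim(fixm))) {  # single-record VCF: vector, not matrix
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF '", path, "' contains no variant records")
  gt_fields <- colnames(vcf@gt)
  if (is.null(gt_fields) || length(gt_fields) < 2) {
    stop("VCF '", path, "' has no genotype columns (GT field required)")
  }
  sex <- toupper(sub("^CHR", "", toupper(fix$CHROM)))
  if (any(sex %in% c("X", "Y"))) {
    stop("X/Y chromosome records are unsupported; remove them upstream (",
         sum(sex %in% c("X", "Y")), " records)")
  }
  drop <- grepl("\\*|<", fix$ALT) | grepl("\\*|<", fix$REF)
  if (any(drop)) {
    message("dropping ", sum(drop), " records with star/symbolic alleles")
    if (all(drop)) stop("no records left after dropping symbolic alleles")
    vcf <- vcf[!drop, ]
    fix <- fix[!drop, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF '", path, "' lacks the GT format field")
  sample_names <- colnames(vcf@gt)[-1]
  gt <- matrix(as.character(gt), nrow = nrow(fix),
               ncol = length(sample_names),
               dimnames = list(NULL, sample_names))
  called <- !is.na(gt) & gt != "." & gt != "./." & gt != ".|."
  phased <- all(grepl("|", gt[called], fixed = TRUE)) && any(called)

  variants <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         filters = ifelse(is.na(fix$FILTER), ".", fix$FILTER),
                         stringsAsFactors = FALSE)
  samples <- reconcile_metadata(colnames(gt), metadata)

  al <- parse_gt_codes(as.vector(gt))
  a1 <- matrix(al$a1, nrow = nrow(variants))
  a2 <- matrix(al$a2, nrow = nrow(variants))
  # biallelic dosage; multi-allelic rows are finalized by split_multiallelic()
  dos <- matrix(as.integer((a1 == 1L) + (a2 == 1L)), nrow = nrow(variants))
  h1 <- if (phased) matrix(as.integer(a1 == 1L), nrow = nrow(variants))
  h2 <- if (phased) matrix(as.integer(a2 == 1L), nrow = nrow(variants))
  multi <- grepl(",", variants$alt, fixed = TRUE)
  if (any(multi)) {
    dos[multi, ] <- NA_integer_
    if (phased) { h1[multi, ] <- NA_integer_; h2[multi, ] <- NA_integer_ }
  }
  variants$variant_class <- rep("SNV", nrow(variants))
  ok <- !multi
  variants$variant_class[ok] <- classify_variant(variants$ref[ok],
                                                 variants$alt[ok])
  ds <- genotype_dataset(variants, samples, dos, hap1 = h1, hap2 = h2,
                         phased = phased)
  attr(ds, "gt_codes") <- gt
  if (split || any(multi)) ds <- split_multiallelic(ds)
  ds
}

reconcile_metadata <- function(vcf_samples, metadata) {
  base <- data.frame(sample_id = vcf_samples, stringsAsFactors = FALSE)
  if (is.null(metadata)) return(base)
  md <- if (is.character(metadata)) read_sample_metadata(metadata)
        else as.data.frame(metadata)
  if (!"sample_id" %in% names(md)) stop("metadata lacks sample_id column")
  extra <- setdiff(md$sample_id, vcf_samples)
  if (length(extra) > 0) {
    stop("metadata samples absent from VCF: ",
         paste(utils::head(extra, 10), collapse = ", "))
  }
  merged <- merge(base, md, by = "sample_id", all.x = TRUE, sort = FALSE)
  merged[match(vcf_samples, merged$sample_id), , drop = FALSE]
}

#' Write a genotype_dataset as VCF v4.2
#'
#' Emits GT (phased `|` genotypes when the dataset is phased) plus AC/AN/AF
#' recomputed from the genotypes in INFO.
#'
#' @param ds genotype_dataset
#' @param path output file
#' @return `path`, invisibly
#' @export
write_vcf <- function(ds, path) {
  v <- ds$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popkit",
    '##INFO=<ID=AC,Number=A,Type=Integer,Description="Alternate allele count in called genotypes">',
    '##INFO=<ID=AN,Number=1,Type=Integer,Description="Number of called allele slots">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Alternate allele frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$samples$sample_id), collapse = "\t")
  )
  af <- ifelse(v$allele_number > 0,
               signif(v$allele_count / v$allele_number, 6), 0)
  info <- paste0("AC=", v$allele_count, ";AN=", v$allele_number, ";AF=", af)
  if (ds$phased) {
    gt <- matrix(paste0(ds$hap1, "|", ds$hap2), nrow = nrow(v))
    gt[is.na(ds$dosages)] <- ".|."
  } else {
    gt <- matrix(c("0/0", "0/1", "1/1")[ds$dosages + 1L], nrow = nrow(v))
    gt[is.na(ds$dosages)] <- "./."
  }
  body <- paste(v$contig, v$pos, ".", v$ref, v$alt, ".",
                ifelse(is.na(v$filters) | v$filters == "", ".", v$filters),
                info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write the sample metadata TSV
#'
#' Tab-separated with header; canonical columns are sample_id, population,
#' region, project, latitude, longitude, mother_id, father_id, mean_coverage.
#'
#' @param path TSV file
#' @return data.frame
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!"sample_id" %in% names(md)) stop("metadata lacks sample_id column")
  md$sample_id <- as.character(md$sample_id)
  md
}

#' @rdname read_sample_metadata
#' @param samples data.frame (e.g. `ds$samples`)
#' @export
write_sample_metadata <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Export the pedigree in PLINK .fam dialect
#'
#' Columns: family (population label, `0` if unknown), individual id,
#' father, mother, sex (0 = unknown), phenotype (-9).
#'
#' @param ds genotype_dataset
#' @param path output file
#' @export
write_fam <- function(ds, path) {
  s <- ds$samples
  fid <- ifelse(is.na(s$population), "0", s$population)
  pat <- ifelse(is.na(s$father_id), "0", s$father_id)
  mat <- ifelse(is.na(s$mother_id), "0", s$mother_id)
  writeLines(paste(fid, s$sample_id, pat, mat, 0L, -9L), path)
  invisible(path)
}

#' Read / write site lists (one `contig:pos:ref:alt` key per line)
#' @param keys character vector of variant keys
#' @param path file path
#' @export
write_site_list <- function(keys, path) {
  writeLines(keys, path)
  invisible(path)
}

#' @rdname write_site_list
#' @export
read_site_list <- function(path) readLines(path)

#' Read / write dosage tables (variant key x sample TSV)
#' @param dosages numeric matrix with variant-key rownames and sample colnames
#' @param path file path
#' @export
write_dosage_tsv <- function(dosages, path) {
  df <- data.frame(variant = rownames(dosages), dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
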