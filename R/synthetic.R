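#' Population and simulation configuration
#'
#' `pop_spec()` describes one population: its region label, sample count,
#' Balding-Nichols divergence F from the shared ancestral pool, and a
#' geographic coordinate. `sim_config()` bundles populations with cohort-wide
#' settings. Pedigree units are planted per population: a trio consumes two
#' founders as parents and adds a child; a duo adds a child with one
#' transmitted parental haplotype and one haplotype drawn fresh from the
#' population frequencies; a duplicate is an exact genotype copy of a founder
#' under a new id (recorded in `duplicate_of`). All randomness flows through
#' `seed`.
#'
#' @param name population label
#' @param region region label (AFR, AMR, CSA, EAS, EUR, MID, OCE or custom)
#' @param n_samples number of founders (>= 1)
#' @param f_divergence Balding-Nichols F, inside (1e-6, 1 - 1e-6)
#' @param latitude,longitude coordinates in degrees
#' @export
pop_spec <- function(name, region, n_samples, f_divergence,
                     latitude, longitude) {
  stopifnot(n_samples >= 1)
  if (f_divergence <= 1e-6 || f_divergence >= 1 - 1e-6) {
    stop("f_divergence must lie in (1e-6, 1 - 1e-6); got ", f_divergence)
  }
  if (latitude < -90 || latitude > 90) stop("latitude outside [-90, 90]")
  if (longitude <= -180 || longitude > 180) stop("longitude outside (-180, 180]")
  structure(list(name = name, region = region,
                 n_samples = as.integer(n_samples),
                 f_divergence = f_divergence,
                 latitude = latitude, longitude = longitude),
            class = "pop_spec")
}

#' Default six-population design
#'
#' Six populations spanning five regions at large-city coordinates, with
#' divergence values in the range typical of continental human populations.
#' These are simulation defaults, not estimates for any real cohort.
#'
#' @param n_samples founders per population (default 25)
#' @export
default_populations <- function(n_samples = 25) {
  list(
    pop_spec("Ibadan",  "AFR", n_samples, 0.05,  7.378,   3.947),
    pop_spec("Utrecht", "EUR", n_samples, 0.10, 52.091,   5.122),
    pop_spec("Cairo",   "MID", n_samples, 0.08, 30.044,  31.236),
    pop_spec("Delhi",   "CSA", n_samples, 0.10, 28.614,  77.209),
    pop_spec("Beijing", "EAS", n_samples, 0.12, 39.904, 116.407),
    pop_spec("Merida",  "AMR", n_samples, 0.15, 20.967, -89.592)
  )
}

#' @rdname pop_spec
#' @param populations list of `pop_spec`
#' @param n_variants number of independent biallelic sites on contig chr1,
#'   spaced 1 kb apart
#' @param ancestral_freq_range interval within (0, 1) for the uniform
#'   ancestral allele frequency
#' @param n_trios,n_duos,n_duplicates pedigree units added per population
#' @param missing_rate per-genotype missingness probability
#' @param ld_block_size when > 1, sites are generated in blocks that copy the
#'   block-head haplotype with per-allele error `ld_copy_error`, creating
#'   strong local LD so pruning has structure to remove (default 1: sites
#'   independent)
#' @param ld_copy_error per-allele copy error within an LD block
#' @param seed integer seed fixing all downstream randomness
#' @export
sim_config <- function(populations = default_populations(),
                       n_variants = 5000,
                       ancestral_freq_range = c(0.05, 0.5),
                       n_trios = 0, n_duos = 0, n_duplicates = 0,
                       missing_rate = 0,
                       ld_block_size = 1, ld_copy_error = 0.02,
                       seed = 1) {
  stopifnot(length(populations) >= 1,
            all(vapply(populations, inherits, TRUE, "pop_spec")),
            n_variants >= 1,
            length(ancestral_freq_range) == 2)
  if (ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1 ||
      ancestral_freq_range[1] >= ancestral_freq_range[2]) {
    stop("ancestral_freq_range must be an increasing interval within (0, 1)")
  }
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate outside [0, 1]")
  for (p in populations) {
    if (p$n_samples < 2 * n_trios + n_duos) {
      stop("population ", p$name, " has ", p$n_samples,
           " founders, too few to host ", n_trios, " trios and ",
           n_duos, " duos")
    }
    if (n_duplicates > p$n_samples) {
      stop("population ", p$name, ": more duplicates than founders")
    }
  }
  structure(list(populations = populations, n_variants = as.integer(n_variants),
                 ancestral_freq_range = ancestral_freq_range,
                 n_trios = as.integer(n_trios), n_duos = as.integer(n_duos),
                 n_duplicates = as.integer(n_duplicates),
                 missing_rate = missing_rate,
                 ld_block_size = as.integer(ld_block_size),
                 ld_copy_error = ld_copy_error,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Balding-Nichols per-population allele frequencies
#'
#' The ancestral frequency p of each variant is Uniform on
#' `ancestral_freq_range`; population k draws its frequency from
#' Beta(p (1 - F_k) / F_k, (1 - p)(1 - F_k) / F_k), so the population
#' frequency has mean p and variance F_k p (1 - p).
#'
#' @param cfg sim_config
#' @param .reseed internal: set FALSE to draw within an already-seeded
#'   stream (used by [simulate_genotypes()])
#' @return list with `ancestral` (length n_variants) and `freqs`
#'   (n_variants x n_populations matrix, columns named by population)
#' @export
simulate_frequencies <- function(cfg, .reseed = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (.reseed) set.seed(cfg$seed)
  p <- stats::runif(cfg$n_variants, cfg$ancestral_freq_range[1],
                    cfg$ancestral_freq_range[2])
  freqs <- vapply(cfg$populations, function(pop) {
    f <- pop$f_divergence
    stats::rbeta(cfg$n_variants, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }, numeric(cfg$n_variants))
  colnames(freqs) <- vapply(cfg$populations, `[[`, "", "name")
  list(ancestral = p, freqs = freqs)
}

#' Simulate a phased genotype cohort with pedigrees
#'
#' Founders are two binomial allele draws per site from their population
#' frequency (haplotypes recorded). Trio children receive one random parental
#' haplotype from each of two founder parents; duo children one transmitted
#' haplotype plus one population draw; duplicates are exact copies under new
#' ids. Missingness is then applied uniformly at `missing_rate`
#' (independently per entry, duplicates included).
#'
#' @param cfg sim_config
#' @param freqs optional result of [simulate_frequencies()]; when NULL the
#'   frequencies are drawn inside the same seeded stream
#' @return phased genotype_dataset; true population frequencies are attached
#'   as attribute `true_freqs`
#' @export
simulate_genotypes <- function(cfg, freqs = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  if (is.null(freqs)) freqs <- simulate_frequencies(cfg, .reseed = FALSE)
  nv <- cfg$n_variants
  h1_all <- list(); h2_all <- list(); meta <- list()

  draw_hap <- function(pf, n) {
    m <- matrix(stats::rbinom(nv * n, 1L, pf), nrow = nv, ncol = n)
    if (cfg$ld_block_size > 1) {
      head_of <- ((seq_len(nv) - 1L) %/% cfg$ld_block_size) *
        cfg$ld_block_size + 1L
      flip <- matrix(stats::rbinom(nv * n, 1L, cfg$ld_copy_error),
                     nrow = nv, ncol = n)
      m <- abs(m[head_of, , drop = FALSE] - flip)
    }
    m
  }

  for (pop in cfg$populations) {
    pf <- freqs$freqs[, pop$name]
    nf <- pop$n_samples
    f1 <- draw_hap(pf, nf); f2 <- draw_hap(pf, nf)
    ids <- sprintf("%s_%03d", pop$name, seq_len(nf))
    mother <- father <- dup_of <- rep(NA_character_, nf)
    h1 <- f1; h2 <- f2
    transmit <- function(p1, p2) {
      pick <- stats::rbinom(nv, 1L, 0.5)
      ifelse(pick == 1L, p1, p2)
    }
    if (cfg$n_trios > 0) {
      for (t in seq_len(cfg$n_trios)) {
        ia <- 2L * t - 1L; ib <- 2L * t
        h1 <- cbind(h1, transmit(f1[, ia], f2[, ia]))
        h2 <- cbind(h2, transmit(f1[, ib], f2[, ib]))
        ids <- c(ids, sprintf("%s_trio%02d_child", pop$name, t))
        mother <- c(mother, sprintf("%s_%03d", pop$name, ia))
        father <- c(father, sprintf("%s_%03d", pop$name, ib))
        dup_of <- c(dup_of, NA_character_)
      }
    }
    if (cfg$n_duos > 0) {
      for (d in seq_len(cfg$n_duos)) {
        ip <- 2L * cfg$n_trios + d
        h1 <- cbind(h1, transmit(f1[, ip], f2[, ip]))
        h2 <- cbind(h2, draw_hap(pf, 1L)[, 1])
        ids <- c(ids, sprintf("%s_duo%02d_child", pop$name, d))
        mother <- c(mother, sprintf("%s_%03d", pop$name, ip))
        father <- c(father, NA_character_)
        dup_of <- c(dup_of, NA_character_)
      }
    }
    if (cfg$n_duplicates > 0) {
      src <- nf - seq_len(cfg$n_duplicates) + 1L  # last founders: not parents
      for (k in seq_along(src)) {
        h1 <- cbind(h1, f1[, src[k]]); h2 <- cbind(h2, f2[, src[k]])
        ids <- c(ids, sprintf("%s_dup%02d", pop$name, k))
        mother <- c(mother, NA_character_); father <- c(father, NA_character_)
        dup_of <- c(dup_of, sprintf("%s_%03d", pop$name, src[k]))
      }
    }
    h1_all[[pop$name]] <- h1; h2_all[[pop$name]] <- h2
    meta[[pop$name]] <- data.frame(
      sample_id = ids, population = pop$name, region = pop$region,
      project = "synthetic", latitude = pop$latitude,
      longitude = pop$longitude, mother_id = mother, father_id = father,
      mean_coverage = NA_real_, duplicate_of = dup_of,
      stringsAsFactors = FALSE)
  }
  hap1 <- do.call(cbind, h1_all); hap2 <- do.call(cbind, h2_all)
  samples <- do.call(rbind, meta); rownames(samples) <- NULL
  dos <- hap1 + hap2
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(length(dos)) < cfg$missing_rate, nrow = nv)
    dos[miss] <- NA_integer_; hap1[miss] <- NA_integer_; hap2[miss] <- NA_integer_
  }
  variants <- data.frame(contig = "chr1", pos = 1000L * seq_len(nv),
                         ref = "A", alt = "G", filters = "PASS",
                         variant_class = "SNV", stringsAsFactors = FALSE)
  ds <- genotype_dataset(variants, samples, dos,
                         hap1 = hap1, hap2 = hap2, phased = TRUE)
  attr(ds, "true_freqs") <- freqs
  ds
}

#' Corrupt phase with a Bernoulli switch process
#'
#' Per sample, at each heterozygous site after the first, the assignment of
#' alleles to the two haplotypes flips with probability `switch_rate`, and
#' the flipped state persists until the next flip (a first-order switch
#' process). Genotypes are unchanged, so downstream switch-error measurement
#' has a known calibration target.
#'
#' @param ds phased genotype_dataset
#' @param switch_rate flip probability in [0, 1]
#' @param seed integer seed
#' @return phased genotype_dataset with corrupted haplotypes
#' @export
corrupt_haplotypes <- function(ds, switch_rate, seed = 1) {
  if (!ds$phased) stop("dataset is not phased")
  if (switch_rate < 0 || switch_rate > 1) stop("switch_rate outside [0, 1]")
  set.seed(seed)
  ord <- order(ds$variants$contig, ds$variants$pos)
  h1 <- ds$hap1; h2 <- ds$hap2
  for (j in seq_len(ncol(h1))) {
    het <- ord[!is.na(ds$dosages[ord, j]) & ds$dosages[ord, j] == 1L]
    if (length(het) < 2) next
    flips <- stats::rbinom(length(het) - 1L, 1L, switch_rate)
    orient <- cumsum(c(0L, flips)) %% 2L
    sw <- het[orient == 1L]
    if (length(sw) > 0) {
      tmp <- h1[sw, j]; h1[sw, j] <- h2[sw, j]; h2[sw, j] <- tmp
    }
  }
  out <- ds
  out$hap1 <- h1; out$hap2 <- h2
  out
}

#' Restrict a dataset to a site list (array-style ascertainment)
#'
#' Emulates genotyping-array or coverage masking by keeping only the listed
#' `contig:pos:ref:alt` keys.
#'
#' @param ds genotype_dataset
#' @param site_keys character vector of variant keys
#' @return genotype_dataset restricted to the intersection
#' @export
mask_to_sites <- function(ds, site_keys) {
  idx <- which(variant_keys(ds) %in% site_keys)
  if (length(idx) == 0) stop("site list shares no variants with the dataset")
  subset_dataset(ds, variant_idx = idx)
}

#' Synthetic imputed dosages with MAF- and coverage-dependent noise
#'
#' Adds Gaussian noise to the true dosages with standard deviation
#' `s0 * exp(-coverage_proxy) * (1 + c / (MAF + eps))`, clipped to \[0, 2\]:
#' noisier at rare variants and low coverage, near-exact at high coverage.
#' This is a noise model standing in for a genotype-imputation engine so
#' accuracy summaries have a controllable target; it is not an imputation
#' method.
#'
#' @param truth genotype_dataset
#' @param coverage_proxy positive sequencing-depth proxy
#' @param seed integer seed
#' @param s0,c,eps noise-model constants
#' @return numeric matrix in \[0, 2\] (NA where truth is missing), with
#'   variant-key rownames and sample colnames
#' @export
simulate_imputed_dosages <- function(truth, coverage_proxy, seed = 1,
                                     s0 = 0.6, c = 0.02, eps = 0.01) {
  if (coverage_proxy <= 0) stop("coverage_proxy must be positive")
  set.seed(seed)
  maf <- variant_maf(truth)
  maf[is.na(maf)] <- 0
  sigma <- s0 * exp(-coverage_proxy) * (1 + c / (maf + eps))
  dos <- truth$dosages
  noise <- matrix(stats::rnorm(length(dos)), nrow = nrow(dos)) * sigma
  imp <- pmin(pmax(dos + noise, 0), 2)
  rownames(imp) <- variant_keys(truth)
  colnames(imp) <- truth$samples$sample_id
  imp
}

#' Write a complete synthetic fixture bundle
#'
#' Simulates a cohort and writes: truth VCF (phased), a phase-corrupted test
#' VCF, sample metadata TSV, PLINK .fam pedigree, two site lists (a random
#' 10% "array" and a common-variant MAF > 0.05 list), an imputed-dosage TSV,
#' and a JSON manifest echoing the config, seed and per-file md5 checksums.
#'
#' @param cfg sim_config
#' @param out_dir output directory (created if needed)
#' @param switch_rate phase-corruption rate for the test VCF
#' @param coverage_proxy depth proxy for the imputed dosages
#' @return named list of file paths, invisibly
#' @export
write_fixture_bundle <- function(cfg, out_dir, switch_rate = 0.02,
                                 coverage_proxy = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_genotypes(cfg)
  corrupted <- corrupt_haplotypes(ds, switch_rate, seed = cfg$seed + 1L)
  paths <- list(
    truth_vcf = file.path(out_dir, "truth.vcf"),
    test_vcf = file.path(out_dir, "test_phased.vcf"),
    metadata = file.path(out_dir, "metadata.tsv"),
    pedigree = file.path(out_dir, "pedigree.fam"),
    sites_random = file.path(out_dir, "array_random.sites"),
    sites_common = file.path(out_dir, "array_common.sites"),
    dosages = file.path(out_dir, "imputed_dosages.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_vcf(ds, paths$truth_vcf)
  write_vcf(corrupted, paths$test_vcf)
  write_sample_metadata(ds$samples, paths$metadata)
  write_fam(ds, paths$pedigree)
  keys <- variant_keys(ds)
  set.seed(cfg$seed + 2L)
  write_site_list(sort(sample(keys, max(1L, round(0.1 * length(keys))))),
                  paths$sites_random)
  write_site_list(keys[!is.na(variant_maf(ds)) & variant_maf(ds) > 0.05],
                  paths$sites_common)
  write_dosage_tsv(simulate_imputed_dosages(ds, coverage_proxy,
                                            seed = cfg$seed + 3L),
                   paths$dosages)
  cfg_echo <- unclass(cfg)
  cfg_echo$populations <- lapply(cfg$populations, unclass)
  manifest <- list(
    seed = cfg$seed, switch_rate = switch_rate,
    coverage_proxy = coverage_proxy, config = cfg_echo,
    files = lapply(paths[names(paths) != "manifest"], function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
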