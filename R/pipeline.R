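#' Run the analysis pipeline end to end
#'
#' Executes the stages in dependency order on a synthetic cohort (or a
#' supplied VCF): simulate -> variant QC -> relatedness partition ->
#' PCA + ancestry model -> divergence vs geography -> phasing/imputation
#' evaluation. Each stage can be toggled in the config; a disabled upstream
#' stage required by an enabled downstream stage is a dependency error
#' before anything runs. Stage outputs are written under `out_dir` as
#' TSV/JSON/VCF, and a JSON manifest (config echo, seed, per-stage wall
#' clock and output checksums) is written even when a stage fails.
#'
#' The config is a nested list (or a YAML file with the same shape):
#' ```
#' seed: 1
#' simulate: {enabled: yes, n_variants: 4000, n_samples: 25, n_trios: 2,
#'            n_duplicates: 1, missing_rate: 0.0005}
#' qc: {enabled: yes}               # relatedness_pca site filter + LD prune
#' relatedness: {enabled: yes}
#' structure: {enabled: yes, k: 10, n_pcs: 10}
#' divergence: {enabled: yes, n_perm: 999}
#' phase_eval: {enabled: yes, switch_rate: 0.02, coverage_proxy: 2}
#' ```
#'
#' @param config list or path to a YAML file
#' @param out_dir output directory
#' @return list of class `run_manifest` (also written as manifest.json)
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  enabled <- function(st) isTRUE(cfg[[st]]$enabled)
  deps <- list(qc = "simulate", relatedness = "qc",
               structure = "relatedness", divergence = "qc",
               phase_eval = "simulate")
  for (st in names(deps)) {
    if (enabled(st) && !enabled(deps[[st]])) {
      stop("stage '", st, "' requires stage '", deps[[st]],
           "' to be enabled", call. = FALSE)
    }
  }
  manifest <- list(seed = cfg$seed, config = cfg, stages = list())
  outputs <- character(0)
  state <- new.env(parent = emptyenv())
  record <- function(stage, t0, files) {
    manifest$stages[[stage]] <<- list(
      seconds = round(as.numeric(Sys.time()) - t0, 2),
      outputs = lapply(files, function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f)))))
    outputs <<- c(outputs, files)
  }
  finish <- function(error = NULL) {
    manifest$error <- error
    path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, force = TRUE)
    structure(manifest, class = c("run_manifest", class(manifest)))
  }
  run <- function() {
    if (enabled("simulate")) {
      t0 <- as.numeric(Sys.time())
      sc <- cfg$simulate
      scfg <- sim_config(
        populations = default_populations(sc$n_samples),
        n_variants = sc$n_variants, n_trios = sc$n_trios,
        n_duos = sc$n_duos, n_duplicates = sc$n_duplicates,
        missing_rate = sc$missing_rate, seed = cfg$seed)
      state$truth <- simulate_genotypes(scfg)
      f <- file.path(out_dir, "cohort.vcf")
      write_vcf(state$truth, f)
      m <- file.path(out_dir, "metadata.tsv")
      write_sample_metadata(state$truth$samples, m)
      record("simulate", t0, c(f, m))
    }
    if (enabled("qc")) {
      t0 <- as.numeric(Sys.time())
      fr <- filter_variants(state$truth, mode = "relatedness_pca")
      keep <- ld_prune(fr$dataset, window = cfg$qc$ld_window,
                       r2_max = cfg$qc$ld_r2_max)
      state$pruned <- subset_dataset(fr$dataset, variant_idx = keep)
      f <- file.path(out_dir, "qc_report.json")
      jsonlite::write_json(
        list(filter = fr$report,
             ld_prune = list(before = nrow(fr$dataset$variants),
                             after = length(keep))),
        f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
      record("qc", t0, f)
    }
    if (enabled("relatedness")) {
      t0 <- as.numeric(Sys.time())
      kt <- king_kinship(state$pruned)
      kt <- classify_pairs(kt)
      state$partition <- unrelated_set(kt)
      f <- file.path(out_dir, "kinship.tsv")
      utils::write.table(kt, f, sep = "\t", quote = FALSE, row.names = FALSE)
      p <- file.path(out_dir, "partition.json")
      jsonlite::write_json(unclass(state$partition), p, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      record("relatedness", t0, c(f, p))
    }
    if (enabled("structure")) {
      t0 <- as.numeric(Sys.time())
      unrel <- subset_dataset(state$pruned,
                              sample_ids = state$partition$unrelated_ids)
      unrel <- filter_variants(unrel, mode = "monomorphic_only")$dataset
      k <- min(cfg$structure$k, nrow(unrel$samples) - 1)
      pca <- fit_pca(unrel, k = k)
      rel_ids <- state$partition$related_ids
      scores_rel <- if (length(rel_ids) > 0) {
        project_samples(pca, subset_dataset(state$pruned,
                                            sample_ids = rel_ids))$scores
      }
      labels <- unrel$samples$region
      am <- train_ancestry_model(pca$scores_train, labels,
                                 n_pcs = min(cfg$structure$n_pcs, k),
                                 seed = cfg$seed)
      f <- file.path(out_dir, "pc_scores.tsv")
      sc <- rbind(pca$scores_train,
                  if (!is.null(scores_rel)) scores_rel)
      utils::write.table(
        data.frame(sample_id = rownames(sc), sc,
                   set = rep(c("unrelated", "projected_related"),
                             c(nrow(pca$scores_train),
                               nrow(sc) - nrow(pca$scores_train)))),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
      state$pca <- pca; state$ancestry <- am
      record("structure", t0, f)
    }
    if (enabled("divergence")) {
      t0 <- as.numeric(Sys.time())
      fst <- fst_pairwise(state$pruned, maf_min = cfg$divergence$maf_min)
      dbl <- count_doubletons(state$truth)
      md <- unique(state$truth$samples[, c("population", "region",
                                           "latitude", "longitude")])
      gd_direct <- geographic_distance_matrix(md, use_waypoints = FALSE)
      gd_way <- geographic_distance_matrix(md, use_waypoints = TRUE)
      corr <- list(
        direct = correlate_fst_geography(fst, gd_direct,
                                         n_perm = cfg$divergence$n_perm,
                                         seed = cfg$seed),
        waypoints = correlate_fst_geography(fst, gd_way,
                                            n_perm = cfg$divergence$n_perm,
                                            seed = cfg$seed))
      f1 <- file.path(out_dir, "fst.tsv")
      utils::write.table(fst$values, f1, sep = "\t", quote = FALSE)
      f2 <- file.path(out_dir, "doubleton_summary.tsv")
      utils::write.table(dbl$summary, f2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f3 <- file.path(out_dir, "geography_correlation.json")
      jsonlite::write_json(corr, f3, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      record("divergence", t0, c(f1, f2, f3))
    }
    if (enabled("phase_eval")) {
      t0 <- as.numeric(Sys.time())
      pe <- cfg$phase_eval
      corrupted <- corrupt_haplotypes(state$truth, pe$switch_rate,
                                      seed = cfg$seed + 1L)
      ser <- switch_error_rate(state$truth, corrupted)
      imp <- simulate_imputed_dosages(state$truth, pe$coverage_proxy,
                                      seed = cfg$seed + 2L)
      r2 <- aggregate_r2(state$truth, imp,
                         bin_edges = c(0.01, 0.05, 0.1, 0.25, 0.5))
      f1 <- file.path(out_dir, "switch_error.tsv")
      utils::write.table(ser$per_sample, f1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f2 <- file.path(out_dir, "aggregate_r2.tsv")
      utils::write.table(as.data.frame(r2), f2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("phase_eval", t0, c(f1, f2))
    }
  }
  err <- NULL
  tryCatch(run(), error = function(e) {
    err <<- conditionMessage(e)
  })
  out <- finish(err)
  if (!is.null(err)) stop("pipeline failed: ", err, call. = FALSE)
  out
}

default_pipeline_config <- function() {
  list(
    seed = 1,
    simulate = list(enabled = TRUE, n_variants = 4000, n_samples = 25,
                    n_trios = 2, n_duos = 0, n_duplicates = 1,
                    missing_rate = 5e-4),
    qc = list(enabled = TRUE, ld_window = 500000, ld_r2_max = 0.1),
    relatedness = list(enabled = TRUE),
    structure = list(enabled = TRUE, k = 10, n_pcs = 10),
    divergence = list(enabled = TRUE, maf_min = 0.05, n_perm = 999),
    phase_eval = list(enabled = TRUE, switch_rate = 0.02,
                      coverage_proxy = 2)
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pipeline run (seed", x$seed, "):\n")
  for (st in names(x$stages)) {
    cat(sprintf("  %-12s %6.2fs  %s\n", st, x$stages[[st]]$seconds,
                paste(vapply(x$stages[[st]]$outputs, `[[`, "", "path"),
                      collapse = ", ")))
  }
  if (!is.null(x$error)) cat("  FAILED:", x$error, "\n")
  invisible(x)
}
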