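# Staged pipeline runner: each stage reads the previous stage's artifacts
# from the output directory, writes its own TSVs plus a JSON manifest
# (parameters, input/output md5 hashes), and fails with a dependency error
# naming any missing upstream file. All randomness flows from one seed.

#' Pipeline configuration
#'
#' Collects paths, stage parameters and the analysis thresholds (all
#' defaulting to the pipeline's standard values: consanguinity F_ROH 0.0156,
#' kinship 0.0884, early-onset age 45, pool filters 100 kb / 100 SNPs, gene
#' flank 1 Mb, allele-frequency ceiling 0.01). Overridden thresholds are
#' echoed to the run log.
#'
#' @param out_dir output directory for stage artifacts.
#' @param sim a [sim_config()] (used by the `simulate` stage).
#' @param roh_params a [roh_call_params()].
#' @param genotype_prefix optional PLINK prefix of real input genotypes; when
#'   `NULL` the `simulate` stage's output is used.
#' @param gene_regions_path optional gene-region TSV.
#' @param variants_path optional annotated-variant TSV for prioritization.
#' @param autosome_kb F_ROH denominator; `NULL` means: use the simulated
#'   map's span when simulating, else [AUTOSOME_KB].
#' @param n_pcs principal components for association adjustment.
#' @param kinship_phi,consanguinity_f,eopd_age,pool_min_kb,pool_min_snps,gene_flank_bp,af_max
#'   analysis thresholds.
#' @param seed integer master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            roh_params = roh_call_params(),
                            genotype_prefix = NULL,
                            gene_regions_path = NULL,
                            variants_path = NULL,
                            autosome_kb = NULL,
                            n_pcs = 5L,
                            kinship_phi = KINSHIP_SECOND_DEGREE,
                            consanguinity_f = CONSANGUINITY_F_ROH,
                            eopd_age = 45,
                            pool_min_kb = 100,
                            pool_min_snps = 100,
                            gene_flank_bp = 1e6,
                            af_max = 0.01,
                            seed = 1L) {
  cfg <- as.list(environment())
  defaults <- c(kinship_phi = KINSHIP_SECOND_DEGREE,
                consanguinity_f = CONSANGUINITY_F_ROH, eopd_age = 45,
                pool_min_kb = 100, pool_min_snps = 100,
                gene_flank_bp = 1e6, af_max = 0.01)
  for (nm in names(defaults)) {
    if (!isTRUE(all.equal(cfg[[nm]], defaults[[nm]]))) {
      inform(sprintf("threshold override: %s = %g (default %g)",
                     nm, cfg[[nm]], defaults[[nm]]))
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `sim` and
#' `roh_params` are nested maps mirroring [sim_config()] and
#' [roh_call_params()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$chrom_lengths_bp)) {
      y$sim$chrom_lengths_bp <- unlist(y$sim$chrom_lengths_bp)
    }
    for (nm in c("maf_range", "planted_length_kb_range")) {
      if (!is.null(y$sim[[nm]])) y$sim[[nm]] <- unlist(y$sim[[nm]])
    }
    y$sim <- do.call(sim_config, y$sim)
  }
  if (!is.null(y$roh_params)) y$roh_params <- do.call(roh_call_params, y$roh_params)
  do.call(pipeline_config, y)
}

artifact_path <- function(config, name) file.path(config$out_dir, name)

require_artifact <- function(config, name, stage) {
  p <- artifact_path(config, name)
  if (!file.exists(p)) {
    abort(sprintf("stage '%s' requires missing artifact: %s", stage, p),
          class = "rohmap_dependency_error")
  }
  p
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  df <- df[!vapply(df, is.list, logical(1))]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(config, stage, inputs, outputs, params = list()) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("rohmap")),
    seed = config$seed,
    parameters = params,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  p <- artifact_path(config, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
  p
}

read_phenotypes <- function(path) {
  df <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
  df$sample_id <- as.character(df$sample_id)
  df
}

load_dataset <- function(config, prefix_name, pheno_name, stage) {
  prefix <- sub("\\.bed$", "", require_artifact(config, paste0(prefix_name, ".bed"), stage))
  ds <- read_plink(prefix)
  pheno <- read_phenotypes(require_artifact(config, pheno_name, stage))
  keep <- intersect(names(pheno), c("sample_id", "sex", "phenotype",
                                    "age_at_sampling", "age_at_onset",
                                    "ancestry_label", "family_id"))
  sheet <- ds$sample_sheet["sample_id"]
  sheet <- left_join(sheet, pheno[keep], by = "sample_id")
  genotype_dataset(ds$genotypes, sheet, ds$variant_map)
}

pipeline_autosome_kb <- function(config, map) {
  if (!is.null(config$autosome_kb)) return(config$autosome_kb)
  if (is.null(config$genotype_prefix)) {
    sum(tapply(map$pos_bp, map$chrom, max)) / 1000
  } else {
    AUTOSOME_KB
  }
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic cohort + truth), `qc` (call rate, kinship,
#' relatedness removal, PCs), `call` (ROH calling on post-call-rate
#' genotypes), `metrics`, `assoc` (burden battery), `map` (pools, exclusivity,
#' enrichment, gene intersection), `families` (segregating ROH), `prioritize`
#' (rare homozygous variants), or `all`. Each stage writes TSV artifacts and
#' a JSON manifest under `config$out_dir` and errors (class
#' `rohmap_dependency_error`) when an upstream artifact is missing.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @return Invisibly, the paths written.
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("simulate", "qc", "call", "metrics", "assoc", "map",
              "families", "prioritize", "all")
  if (!stage %in% stages) {
    abort(sprintf("unknown stage '%s'", stage), class = "rohmap_validation_error")
  }
  if (stage == "all") {
    todo <- setdiff(stages, "all")
    if (!is.null(config$genotype_prefix)) todo <- setdiff(todo, "simulate")
    if (is.null(config$variants_path)) todo <- setdiff(todo, "prioritize")
    out <- unlist(lapply(todo, run_stage, config = config))
    return(invisible(out))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  paths <- switch(stage,
    simulate = stage_simulate(config),
    qc = stage_qc(config),
    call = stage_call(config),
    metrics = stage_metrics(config),
    assoc = stage_assoc(config),
    map = stage_map(config),
    families = stage_families(config),
    prioritize = stage_prioritize(config)
  )
  inform(sprintf("stage '%s' done in %.1fs", stage,
                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(paths)
}

stage_simulate <- function(config) {
  sim <- config$sim
  sim$seed <- config$seed
  res <- simulate_cohort(sim)
  prefix <- artifact_path(config, "cohort")
  write_plink(res$dataset, prefix)
  p_pheno <- write_tsv(res$dataset$sample_sheet,
                       artifact_path(config, "phenotypes.tsv"))
  p_truth <- write_tsv(res$truth$planted_segments,
                       artifact_path(config, "truth_segments.tsv"))
  p_carr <- write_tsv(res$truth$carrier_table,
                      artifact_path(config, "truth_carriers.tsv"))
  outs <- c(paste0(prefix, c(".bed", ".bim", ".fam")), p_pheno, p_truth, p_carr)
  write_manifest(config, "simulate", character(), outs,
                 params = unclass(sim)[!vapply(unclass(sim), is.list, logical(1))])
  outs
}

stage_qc <- function(config) {
  if (!is.null(config$genotype_prefix)) {
    ds <- read_plink(config$genotype_prefix)
    pheno_path <- NULL
  } else {
    ds <- load_dataset(config, "cohort", "phenotypes.tsv", "qc")
    pheno_path <- artifact_path(config, "phenotypes.tsv")
  }
  ds <- filter_call_rate(ds)
  kin <- king_kinship_all(ds)
  ds <- remove_related(ds, kin, phi_max = config$kinship_phi)
  p_kin <- write_tsv(kin, artifact_path(config, "kinship.tsv"))
  prefix <- artifact_path(config, "qc")
  write_plink(ds, prefix)
  p_sheet <- write_tsv(ds$sample_sheet, artifact_path(config, "qc_samples.tsv"))
  pcs <- if (config$n_pcs > 0) {
    pruned <- ld_prune(maf_filter(ds))
    compute_pcs(pruned, n_pcs = config$n_pcs)
  } else {
    tibble(sample_id = ds$sample_sheet$sample_id)
  }
  p_pcs <- write_tsv(pcs, artifact_path(config, "pcs.tsv"))
  outs <- c(paste0(prefix, c(".bed", ".bim", ".fam")), p_kin, p_sheet, p_pcs)
  write_manifest(config, "qc", c(pheno_path), outs,
                 params = list(kinship_phi = config$kinship_phi,
                               n_pcs = config$n_pcs))
  outs
}

stage_call <- function(config) {
  ds <- load_dataset(config, "qc", "qc_samples.tsv", "call")
  segs <- call_roh_cohort(ds, config$roh_params)
  p_segs <- write_tsv(segs, artifact_path(config, "segments.tsv"))
  p_bed <- write_segments_bed(segs, artifact_path(config, "segments.bed"))
  outs <- c(p_segs, p_bed)
  write_manifest(config, "call", artifact_path(config, "qc.bed"), outs,
                 params = unclass(config$roh_params))
  outs
}

read_segments_tsv <- function(path) {
  df <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
  df$sample_id <- as.character(df$sample_id)
  df
}

stage_metrics <- function(config) {
  p_in <- require_artifact(config, "segments.tsv", "metrics")
  segs <- read_segments_tsv(p_in)
  sheet <- read_phenotypes(require_artifact(config, "qc_samples.tsv", "metrics"))
  ds_map <- read_plink(sub("\\.bed$", "", require_artifact(config, "qc.bed", "metrics")))
  akb <- pipeline_autosome_kb(config, ds_map$variant_map)
  mets <- summarize_roh(segs, sample_ids = sheet$sample_id, autosome_kb = akb)
  p_out <- write_tsv(mets, artifact_path(config, "metrics.tsv"))
  write_manifest(config, "metrics", p_in, p_out,
                 params = list(autosome_kb = akb))
  p_out
}

stage_assoc <- function(config) {
  p_met <- require_artifact(config, "metrics.tsv", "assoc")
  p_seg <- require_artifact(config, "segments.tsv", "assoc")
  segs <- read_segments_tsv(p_seg)
  sheet <- read_phenotypes(require_artifact(config, "qc_samples.tsv", "assoc"))
  pcs <- read_phenotypes(require_artifact(config, "pcs.tsv", "assoc"))
  regions <- if (!is.null(config$gene_regions_path)) {
    read_gene_regions(config$gene_regions_path)
  }
  ds_map <- read_plink(sub("\\.bed$", "", require_artifact(config, "qc.bed", "assoc")))
  akb <- pipeline_autosome_kb(config, ds_map$variant_map)
  sheet <- impute_missing_aao(sheet)
  battery <- run_association_battery(segs, sheet, pcs,
                                     recessive_regions = regions,
                                     autosome_kb = akb)
  p_out <- write_tsv(battery, artifact_path(config, "association.tsv"))
  write_manifest(config, "assoc", c(p_met, p_seg), p_out)
  p_out
}

stage_map <- function(config) {
  p_seg <- require_artifact(config, "segments.tsv", "map")
  segs <- read_segments_tsv(p_seg)
  sheet <- read_phenotypes(require_artifact(config, "qc_samples.tsv", "map"))
  ds_map <- read_plink(sub("\\.bed$", "", require_artifact(config, "qc.bed", "map")))
  pools <- build_pools(segs, ds_map$variant_map)
  pools <- filter_pools(pools, config$pool_min_kb, config$pool_min_snps)
  pools <- flag_case_exclusive(pools, segs, sheet)
  n_cases <- sum(sheet$phenotype == "case")
  n_controls <- sum(sheet$phenotype == "control")
  pools <- test_pool_enrichment(pools, n_cases, n_controls)
  p_pools <- write_tsv(pools, artifact_path(config, "pools.tsv"))
  outs <- p_pools
  if (!is.null(config$gene_regions_path)) {
    ov <- intersect_gene_regions(pools, read_gene_regions(config$gene_regions_path),
                                 flank_bp = config$gene_flank_bp)
    outs <- c(outs, write_tsv(ov, artifact_path(config, "gene_overlaps.tsv")))
  }
  write_manifest(config, "map", p_seg, outs,
                 params = list(pool_min_kb = config$pool_min_kb,
                               pool_min_snps = config$pool_min_snps))
  outs
}

# The family branch keeps related individuals: it re-calls ROH on the
# call-rate-filtered cohort after variant-level missingness (5%) and
# Hardy-Weinberg (1e-10) filters, then tests segregation within
# kinship-inferred families.
stage_families <- function(config) {
  p_kin <- require_artifact(config, "kinship.tsv", "families")
  kin <- as_tibble(read.table(p_kin, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
  if (!is.null(config$genotype_prefix)) {
    ds <- read_plink(config$genotype_prefix)
  } else {
    ds <- load_dataset(config, "cohort", "phenotypes.tsv", "families")
  }
  ds <- filter_call_rate(ds)
  vmiss <- colMeans(is.na(ds$genotypes))
  ds <- subset_dataset(ds, variants = which(vmiss <= 0.05))
  ds <- hwe_filter(ds, alpha = 1e-10)
  segs <- call_roh_cohort(ds, config$roh_params)
  pools <- build_pools(segs, ds$variant_map)
  pools <- filter_pools(pools, config$pool_min_kb, config$pool_min_snps)
  pools <- flag_case_exclusive(pools, segs, ds$sample_sheet)
  hits <- family_segregation(pools, ds, kin, phi_min = config$kinship_phi)
  hits$member_ids <- vapply(hits$member_ids, paste, character(1), collapse = ",")
  p_out <- write_tsv(hits, artifact_path(config, "family_hits.tsv"))
  write_manifest(config, "families", p_kin, p_out)
  p_out
}

stage_prioritize <- function(config) {
  if (is.null(config$variants_path)) {
    abort("stage 'prioritize' requires config$variants_path",
          class = "rohmap_dependency_error")
  }
  p_seg <- require_artifact(config, "segments.tsv", "prioritize")
  segs <- read_segments_tsv(p_seg)
  ds_map <- read_plink(sub("\\.bed$", "", require_artifact(config, "qc.bed", "prioritize")))
  pools <- build_pools(segs, ds_map$variant_map)
  pools <- filter_pools(pools, config$pool_min_kb, config$pool_min_snps)
  variants <- read_annotated_variants(config$variants_path)
  cand <- prioritize_variants(variants, pools, af_max = config$af_max)
  cand <- rank_candidates(cand)
  cand$n_carriers_listed <- vapply(cand$genotypes, length, integer(1))
  p_out <- write_tsv(cand, artifact_path(config, "candidates.tsv"))
  write_manifest(config, "prioritize", c(p_seg, config$variants_path), p_out,
                 params = list(af_max = config$af_max))
  p_out
}

#' Run the whole pipeline
#'
#' Convenience wrapper for `run_stage("all", config)`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the artifact paths written.
#' @export
run_pipeline <- function(config) run_stage("all", config)
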