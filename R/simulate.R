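# Synthetic cohort generator: SNP-array-density genotypes in Hardy-Weinberg
# proportions with planted homozygous segments (background ROH, consanguinity,
# family-shared ROH, a case-enriched risk locus), genotyping error and
# missingness. SNPs are simulated without linkage disequilibrium, matching the
# post-pruning substrate the downstream analyses assume.

#' Simulation configuration
#'
#' Assembles and validates the parameters of [simulate_cohort()]. Defaults are
#' the package's study conditions: 20 kb mean marker spacing (array density),
#' allele frequencies uniform on 0.05-0.5, heterozygous-call error rate
#' 5e-4 inside planted segments, 0.002 missingness, consanguinity target
#' F_ROH 0.05.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param chrom_lengths_bp named numeric vector of chromosome lengths in bp;
#'   names are autosome numbers.
#' @param snp_spacing_mean_bp mean inter-SNP gap (exponential spacing).
#' @param maf_range allele-2 frequency range sampled per SNP.
#' @param background_roh_rate expected planted background segments per
#'   individual (Poisson).
#' @param planted_length_kb_range min/max planted segment length in kb; the
#'   minimum must be >= 1500 so planted truth segments are recoverable.
#' @param het_error_rate per-SNP probability a planted homozygous call is
#'   recorded heterozygous.
#' @param missing_rate per-genotype missingness probability.
#' @param n_consanguineous_cases cases planted to the consanguinity target.
#' @param consanguineous_f_target target F_ROH for those cases.
#' @param n_families,family_size families of affected relatives sharing a
#'   planted segregating segment.
#' @param eopd_fraction fraction of cases assigned early onset (age at onset
#'   under 45 years).
#' @param risk_locus `NULL` or a list with `chrom`, `start_bp`, `end_bp`,
#'   `p_carrier_case`, `p_carrier_control`: a locus where carriers receive a
#'   planted homozygous segment.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 100,
                       n_controls = 100,
                       chrom_lengths_bp = c(`1` = 60e6, `2` = 50e6,
                                            `3` = 40e6, `4` = 30e6),
                       snp_spacing_mean_bp = 20000,
                       maf_range = c(0.05, 0.5),
                       background_roh_rate = 1,
                       planted_length_kb_range = c(2000, 5000),
                       het_error_rate = 5e-4,
                       missing_rate = 0.002,
                       n_consanguineous_cases = 0,
                       consanguineous_f_target = 0.05,
                       n_families = 0,
                       family_size = 3,
                       eopd_fraction = 0.25,
                       risk_locus = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$het_error_rate, cfg$missing_rate, cfg$eopd_fraction)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (cfg$planted_length_kb_range[1] < 1500) {
    abort("planted_length_kb_range minimum must be >= 1500 kb")
  }
  if (is.null(names(cfg$chrom_lengths_bp))) {
    names(cfg$chrom_lengths_bp) <- seq_along(cfg$chrom_lengths_bp)
  }
  chroms <- as.integer(names(cfg$chrom_lengths_bp))
  if (any(is.na(chroms)) || any(chroms < 1L | chroms > 22L)) {
    abort("chrom_lengths_bp names must be autosomes 1-22")
  }
  if (!is.null(cfg$risk_locus)) {
    rl <- cfg$risk_locus
    need <- c("chrom", "start_bp", "end_bp", "p_carrier_case", "p_carrier_control")
    if (!all(need %in% names(rl))) {
      abort(paste("risk_locus needs fields:", paste(need, collapse = ", ")))
    }
    if (!as.integer(rl$chrom) %in% chroms ||
        rl$end_bp > cfg$chrom_lengths_bp[[as.character(rl$chrom)]]) {
      abort("risk_locus lies outside the simulated chromosomes")
    }
  }
  structure(cfg, class = "sim_config")
}

empty_truth <- function() {
  list(
    planted_segments = tibble(
      sample_id = character(), chrom = integer(),
      start_bp = integer(), end_bp = integer(), kind = character()
    ),
    carrier_table = tibble(sample_id = character(), risk_carrier = logical())
  )
}

# Overwrite genotypes in [start_bp, end_bp] with homozygous calls, the allele
# drawn Bernoulli(allele-2 freq) per locus. Returns updated genotype matrix.
plant_homozygous <- function(genotypes, map, freqs, sample_idx, chrom, start_bp, end_bp) {
  idx <- which(map$chrom == chrom & map$pos_bp >= start_bp & map$pos_bp <= end_bp)
  if (length(idx)) {
    genotypes[sample_idx, idx] <- 2L * rbinom(length(idx), 1L, freqs[idx])
  }
  genotypes
}

# TRUE if [s, e] overlaps any planted interval of this sample on this chrom.
overlaps_planted <- function(truth, sample_id, chrom, s, e) {
  ps <- truth$planted_segments
  any(ps$sample_id == sample_id & ps$chrom == chrom &
        ps$start_bp <= e & ps$end_bp >= s)
}

#' Simulate a case-control cohort with planted runs of homozygosity
#'
#' Generates a [genotype_dataset()] and a ground-truth ledger. Variant
#' positions are cumulative exponential gaps truncated at each chromosome
#' length; allele-2 frequencies are uniform on `maf_range`; background
#' genotypes follow Hardy-Weinberg proportions. Planted segments (background,
#' consanguinity, family, risk locus) overwrite genotypes with homozygous
#' calls, then heterozygous-call errors are injected inside planted segments
#' and missingness applied genome-wide. Ages at sampling are Normal(62, 10)
#' clipped to 18-90; early-onset cases receive an age at onset below 45.
#'
#' @param config a [sim_config()].
#' @return A list with `dataset` (a [genotype_dataset()]) and `truth`
#'   (tibbles `planted_segments` and `carrier_table`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- as.integer(names(config$chrom_lengths_bp))

  # marker map
  map_list <- lapply(seq_along(chroms), function(ci) {
    len <- config$chrom_lengths_bp[[ci]]
    n_guess <- ceiling(len / config$snp_spacing_mean_bp * 1.4) + 50L
    pos <- cumsum(ceiling(rexp(n_guess, 1 / config$snp_spacing_mean_bp)))
    pos <- unique(pos[pos <= len])
    tibble(chrom = chroms[ci], pos_bp = as.integer(pos))
  })
  map <- bind_rows(map_list)
  map$variant_id <- sprintf("snp_%d_%d", map$chrom, map$pos_bp)
  map$allele1 <- "A"
  map$allele2 <- "B"
  m <- nrow(map)
  freqs <- runif(m, config$maf_range[1], config$maf_range[2])

  n <- config$n_cases + config$n_controls
  ids <- sprintf("S%04d", seq_len(n))
  phenotype <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  sheet <- tibble(
    sample_id = ids, family_id = ids,
    sex = rep_len(c("male", "female"), n),
    phenotype = phenotype,
    age_at_sampling = pmin(pmax(rnorm(n, 62, 10), 18), 90),
    age_at_onset = NA_real_,
    ancestry_label = "SIM"
  )
  # onset: a fixed fraction of cases early-onset (<45), the rest late-onset
  case_idx <- which(phenotype == "case")
  n_eopd <- round(config$eopd_fraction * length(case_idx))
  eopd_idx <- head(case_idx, n_eopd)
  lopd_idx <- setdiff(case_idx, eopd_idx)
  sheet$age_at_onset[eopd_idx] <- pmin(pmax(rnorm(length(eopd_idx), 38, 5), 18), 44.9)
  sheet$age_at_onset[lopd_idx] <- pmin(pmax(rnorm(length(lopd_idx), 58, 8), 45), 85)
  sheet$age_at_sampling[case_idx] <-
    pmin(sheet$age_at_onset[case_idx] + runif(length(case_idx), 0, 15), 90)

  genotypes <- matrix(rbinom(n * m, 2L, rep(freqs, each = n)), n, m)
  truth <- empty_truth()
  truth$carrier_table <- tibble(sample_id = ids, risk_carrier = FALSE)

  # families: affected relatives built from a shared template, then a shared
  # segregating homozygous segment planted across the members
  fam_members <- list()
  if (config$n_families > 0) {
    n_fam_samples <- config$n_families * config$family_size
    fam_pool <- tail(case_idx, n_fam_samples)
    if (length(fam_pool) < n_fam_samples) abort("not enough cases for the requested families")
    for (f in seq_len(config$n_families)) {
      members <- fam_pool[((f - 1) * config$family_size + 1):(f * config$family_size)]
      template <- rbinom(m, 2L, freqs)
      for (s in members) {
        share <- runif(m) < 0.5
        genotypes[s, ] <- ifelse(share, template, rbinom(m, 2L, freqs))
      }
      sheet$family_id[members] <- sprintf("FAM%02d", f)
      fam_members[[f]] <- ids[members]
    }
  }

  dataset <- genotype_dataset(genotypes, sheet, map)

  # consanguineous cases: planted segments until F_ROH target reached
  if (config$n_consanguineous_cases > 0) {
    for (s in ids[head(case_idx, config$n_consanguineous_cases)]) {
      res <- make_consanguineous(dataset, truth, s,
                                 f_target = config$consanguineous_f_target,
                                 length_kb_range = config$planted_length_kb_range,
                                 freqs = freqs)
      dataset <- res$dataset
      truth <- res$truth
    }
  }

  # family segregating segments
  if (config$n_families > 0) {
    for (f in seq_len(config$n_families)) {
      chrom <- chroms[sample.int(length(chroms), 1, prob = config$chrom_lengths_bp)]
      len <- runif(1, 2e6, 4e6)
      start <- floor(runif(1, 1, config$chrom_lengths_bp[[as.character(chrom)]] - len))
      region <- list(chrom = chrom, start_bp = as.integer(start),
                     end_bp = as.integer(start + len))
      res <- plant_family_roh(dataset, truth, fam_members[[f]], region, freqs = freqs)
      dataset <- res$dataset
      truth <- res$truth
    }
  }

  # background ROH
  n_bg <- rpois(n, config$background_roh_rate)
  for (i in seq_len(n)) {
    planted <- 0L
    tries <- 0L
    while (planted < n_bg[i] && tries < 50L) {
      tries <- tries + 1L
      chrom <- chroms[sample.int(length(chroms), 1, prob = config$chrom_lengths_bp)]
      len <- runif(1, config$planted_length_kb_range[1],
                   config$planted_length_kb_range[2]) * 1000
      clen <- config$chrom_lengths_bp[[as.character(chrom)]]
      if (len >= clen) next
      start <- floor(runif(1, 1, clen - len))
      end <- as.integer(start + len)
      if (overlaps_planted(truth, ids[i], chrom, start, end)) next
      dataset$genotypes <- plant_homozygous(dataset$genotypes, map, freqs,
                                            i, chrom, start, end)
      truth$planted_segments <- bind_rows(
        truth$planted_segments,
        tibble(sample_id = ids[i], chrom = chrom, start_bp = as.integer(start),
               end_bp = end, kind = "background")
      )
      planted <- planted + 1L
    }
  }

  # risk locus: carriers by case/control status, planted span jittered outward
  if (!is.null(config$risk_locus)) {
    rl <- config$risk_locus
    p_carrier <- ifelse(phenotype == "case", rl$p_carrier_case, rl$p_carrier_control)
    carrier <- runif(n) < p_carrier
    truth$carrier_table$risk_carrier <- carrier
    clen <- config$chrom_lengths_bp[[as.character(rl$chrom)]]
    for (i in which(carrier)) {
      s <- max(1, rl$start_bp - floor(runif(1, 0, 5e5)))
      e <- min(clen, rl$end_bp + floor(runif(1, 0, 5e5)))
      dataset$genotypes <- plant_homozygous(dataset$genotypes, map, freqs,
                                            i, rl$chrom, s, e)
      truth$planted_segments <- bind_rows(
        truth$planted_segments,
        tibble(sample_id = ids[i], chrom = as.integer(rl$chrom),
               start_bp = as.integer(s), end_bp = as.integer(e),
               kind = "risk_locus")
      )
    }
  }

  # heterozygous-call errors inside planted segments, then missingness
  if (config$het_error_rate > 0 && nrow(truth$planted_segments) > 0) {
    for (k in seq_len(nrow(truth$planted_segments))) {
      seg <- truth$planted_segments[k, ]
      i <- match(seg$sample_id, ids)
      idx <- which(map$chrom == seg$chrom & map$pos_bp >= seg$start_bp &
                     map$pos_bp <= seg$end_bp)
      flip <- idx[runif(length(idx)) < config$het_error_rate]
      dataset$genotypes[i, flip] <- 1L
    }
  }
  if (config$missing_rate > 0) {
    miss <- matrix(runif(n * m) < config$missing_rate, n, m)
    dataset$genotypes[miss] <- NA_integer_
  }

  list(dataset = dataset, truth = truth)
}

#' Plant a family-segregating run of homozygosity
#'
#' Gives every listed family member identical homozygous genotypes (the same
#' allele at every SNP) across `region`, so the pairwise allelic match over
#' the region is exactly 1 before any error injection.
#'
#' @param dataset a [genotype_dataset()].
#' @param truth a truth list as returned by [simulate_cohort()].
#' @param family_ids character vector of member sample ids.
#' @param region list with `chrom`, `start_bp`, `end_bp`.
#' @param freqs optional per-variant allele-2 frequencies used to draw the
#'   shared allele; estimated from the cohort when omitted.
#' @return List with updated `dataset` and `truth`.
#' @export
plant_family_roh <- function(dataset, truth, family_ids, region, freqs = NULL) {
  if (length(family_ids) == 0) return(list(dataset = dataset, truth = truth))
  rows <- match(family_ids, dataset$sample_sheet$sample_id)
  if (anyNA(rows)) {
    abort(paste("unknown sample id(s):",
                paste(family_ids[is.na(rows)], collapse = ", ")))
  }
  map <- dataset$variant_map
  idx <- which(map$chrom == region$chrom & map$pos_bp >= region$start_bp &
                 map$pos_bp <= region$end_bp)
  if (length(idx) == 0) abort("region contains no SNPs in the variant map")
  if (is.null(freqs)) freqs <- allele2_freq(dataset$genotypes)
  shared <- 2L * rbinom(length(idx), 1L, pmin(pmax(freqs[idx], 0), 1))
  for (r in rows) dataset$genotypes[r, idx] <- shared
  truth$planted_segments <- bind_rows(
    truth$planted_segments,
    tibble(sample_id = family_ids, chrom = as.integer(region$chrom),
           start_bp = as.integer(region$start_bp),
           end_bp = as.integer(region$end_bp), kind = "family")
  )
  list(dataset = dataset, truth = truth)
}

#' Plant consanguinity-level homozygosity into one sample
#'
#' Plants disjoint homozygous segments (lengths uniform on `length_kb_range`)
#' until the planted total reaches `f_target` times the simulated autosome
#' length (the per-chromosome span of the variant map).
#'
#' @inheritParams plant_family_roh
#' @param sample_id the sample to modify.
#' @param f_target target genomic inbreeding fraction, in (0, 0.25].
#' @param length_kb_range planted segment length range in kb.
#' @return List with updated `dataset` and `truth`.
#' @export
make_consanguineous <- function(dataset, truth, sample_id, f_target = 0.05,
                                length_kb_range = c(2000, 5000), freqs = NULL) {
  if (!is.numeric(f_target) || f_target <= 0 || f_target > 0.25) {
    abort("f_target must lie in (0, 0.25]")
  }
  row <- match(sample_id, dataset$sample_sheet$sample_id)
  if (is.na(row)) abort(paste("unknown sample id:", sample_id))
  map <- dataset$variant_map
  if (is.null(freqs)) freqs <- allele2_freq(dataset$genotypes)
  chrom_span <- tapply(map$pos_bp, map$chrom, max)
  genome_bp <- sum(chrom_span)
  target_bp <- f_target * genome_bp
  planted_bp <- 0
  tries <- 0L
  while (planted_bp < target_bp) {
    tries <- tries + 1L
    if (tries > 500L) abort("insufficient genome space to reach f_target")
    chrom <- as.integer(sample(names(chrom_span), 1, prob = chrom_span))
    len <- runif(1, length_kb_range[1], length_kb_range[2]) * 1000
    clen <- chrom_span[[as.character(chrom)]]
    if (len >= clen) next
    start <- floor(runif(1, 1, clen - len))
    end <- as.integer(start + len)
    if (overlaps_planted(truth, sample_id, chrom, start, end)) next
    dataset$genotypes <- plant_homozygous(dataset$genotypes, map, freqs,
                                          row, chrom, start, end)
    truth$planted_segments <- bind_rows(
      truth$planted_segments,
      tibble(sample_id = sample_id, chrom = chrom,
             start_bp = as.integer(start), end_bp = end,
             kind = "consanguinity")
    )
    planted_bp <- planted_bp + (end - start + 1)
  }
  list(dataset = dataset, truth = truth)
}
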