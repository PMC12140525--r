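# Per-individual homozygosity summary metrics and consanguinity
# classification: S_ROH (total length), N_ROH (count), AV_ROH (mean length),
# F_ROH (genomic inbreeding coefficient = S_ROH / autosomal genome length).

#' Summarize runs of homozygosity per individual
#'
#' Computes `s_roh_kb` (total segment length), `n_roh` (segment count),
#' `av_roh_kb` (= S/N, 0 when no segments), `f_roh` (= S / `autosome_kb`) and
#' the consanguinity flag (`f_roh > 0.0156`, strict) for each sample.
#'
#' @param segments segment tibble from [call_roh_cohort()].
#' @param sample_ids optional ids to include with zero metrics when they have
#'   no segments.
#' @param autosome_kb autosomal genome length in kb; defaults to the
#'   GRCh38.p14 constant [AUTOSOME_KB], override for simulated genomes.
#' @return Tibble with `sample_id`, `s_roh_kb`, `n_roh`, `av_roh_kb`,
#'   `f_roh`, `consanguineous`.
#' @export
summarize_roh <- function(segments, sample_ids = NULL,
                          autosome_kb = AUTOSOME_KB) {
  if (!is.numeric(autosome_kb) || autosome_kb <= 0) {
    abort("autosome_kb must be positive")
  }
  agg <- segments |>
    group_by(.data$sample_id) |>
    summarise(s_roh_kb = sum(.data$length_kb), n_roh = n(), .groups = "drop")
  ids <- union(if (is.null(sample_ids)) character() else sample_ids,
               agg$sample_id)
  out <- tibble(sample_id = ids) |>
    left_join(agg, by = "sample_id") |>
    mutate(
      s_roh_kb = ifelse(is.na(.data$s_roh_kb), 0, .data$s_roh_kb),
      n_roh = ifelse(is.na(.data$n_roh), 0L, .data$n_roh),
      av_roh_kb = ifelse(.data$n_roh > 0, .data$s_roh_kb / .data$n_roh, 0),
      f_roh = .data$s_roh_kb / autosome_kb,
      consanguineous = classify_consanguinity(.data$f_roh)
    )
  arrange(out, .data$sample_id)
}

#' Classify consanguinity from the genomic inbreeding coefficient
#'
#' TRUE iff `f_roh` strictly exceeds 0.0156, the inbreeding coefficient of
#' second-cousin offspring (a second-degree parental relation, (1/2)^6
#' rounded to three significant figures). A value exactly at the threshold is
#' not consanguineous.
#'
#' @param f_roh numeric vector of genomic inbreeding coefficients in [0, 1].
#' @return Logical vector.
#' @export
classify_consanguinity <- function(f_roh) {
  if (any(is.na(f_roh)) || any(f_roh < 0 | f_roh > 1)) {
    abort("f_roh must lie in [0, 1]")
  }
  f_roh > CONSANGUINITY_F_ROH
}

#' Subset segments by a minimum length threshold
#'
#' Retains segments strictly longer than `min_mb` megabases; downstream
#' metrics (notably AV_ROH) are recomputed on the subset. The pipeline sweeps
#' thresholds from >2 Mb to >10 Mb in 1 Mb increments.
#'
#' @param segments segment tibble.
#' @param min_mb strict lower bound in Mb.
#' @return Filtered segment tibble.
#' @export
subset_by_min_length <- function(segments, min_mb) {
  filter(segments, .data$length_kb > min_mb * 1000)
}

#' Exclude segments overlapping gene regions
#'
#' Removes (or truncates around) segments that overlap any supplied region
#' expanded by `flank_bp` on each side — used to drop the known recessive
#' Parkinson's disease genes (PRKN, DJ-1/PARK7, PINK1) from burden analyses.
#' Whole-segment removal is the default, the conservative choice for burden
#' testing.
#'
#' @param segments segment tibble.
#' @param regions tibble from [read_gene_regions()].
#' @param flank_bp flank added to each region side.
#' @param mode `"remove"` drops overlapping segments entirely; `"truncate"`
#'   clips segments to the parts outside the flanked regions.
#' @return Filtered segment tibble.
#' @export
exclude_gene_regions <- function(segments, regions, flank_bp = 1e6,
                                 mode = c("remove", "truncate")) {
  mode <- match.arg(mode)
  if (nrow(segments) == 0 || nrow(regions) == 0) return(segments)
  hit <- rep(FALSE, nrow(segments))
  for (k in seq_len(nrow(regions))) {
    lo <- regions$start_bp[k] - flank_bp
    hi <- regions$end_bp[k] + flank_bp
    hit <- hit | (segments$chrom == regions$chrom[k] &
                    segments$start_bp <= hi & segments$end_bp >= lo)
  }
  if (mode == "remove") return(segments[!hit, , drop = FALSE])
  out <- segments[!hit, , drop = FALSE]
  for (i in which(hit)) {
    pieces <- tibble(start_bp = segments$start_bp[i], end_bp = segments$end_bp[i])
    for (k in which(regions$chrom == segments$chrom[i])) {
      lo <- regions$start_bp[k] - flank_bp
      hi <- regions$end_bp[k] + flank_bp
      pieces <- bind_rows(lapply(seq_len(nrow(pieces)), function(j) {
        s <- pieces$start_bp[j]; e <- pieces$end_bp[j]
        if (e < lo || s > hi) return(tibble(start_bp = s, end_bp = e))
        bind_rows(
          if (s < lo) tibble(start_bp = s, end_bp = lo - 1) else NULL,
          if (e > hi) tibble(start_bp = hi + 1, end_bp = e) else NULL
        )
      }))
    }
    if (nrow(pieces)) {
      add <- segments[rep(i, nrow(pieces)), , drop = FALSE]
      add$start_bp <- pieces$start_bp
      add$end_bp <- pieces$end_bp
      add$length_kb <- (add$end_bp - add$start_bp + 1) / 1000
      add$n_snps <- NA_integer_  # SNP counts are undefined after truncation
      out <- bind_rows(out, add)
    }
  }
  arrange(out, .data$sample_id, .data$chrom, .data$start_bp)
}
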