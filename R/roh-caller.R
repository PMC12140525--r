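# Sliding-window run-of-homozygosity caller.
#
# A 50-SNP window slides one SNP at a time along each autosome; a window is
# "homozygous" if it holds at most 1 heterozygous and at most 5 missing
# calls. A SNP is marked when the fraction of homozygous windows among the
# windows containing it reaches 5%. Maximal runs of marked SNPs, split at
# inter-SNP gaps over 1 Mb, become segments if they hold >= 100 SNPs, span
# > 1,500 kb and average at most 50 kb per SNP.

#' ROH calling parameters
#'
#' Defaults are the package's standard array-density calling parameters:
#' 50-SNP windows allowing 1 heterozygous and 5 missing calls, a 5%
#' homozygous-window hit threshold per SNP, minimum 100 SNPs and a strict
#' \eqn{>1{,}500} kb length cut-off per segment, a 1 Mb maximum gap between
#' consecutive SNPs, and a minimum density of one SNP per 50 kb.
#'
#' @param window_snps SNPs per sliding window.
#' @param window_max_het maximum heterozygous calls per homozygous window.
#' @param window_max_missing maximum missing calls per homozygous window.
#' @param snp_hit_threshold minimum fraction of homozygous windows covering a
#'   SNP for it to be marked.
#' @param min_snps minimum SNPs per segment.
#' @param min_length_kb strict lower bound on segment length (kb).
#' @param max_gap_kb maximum gap between consecutive segment SNPs (kb).
#' @param max_kb_per_snp maximum segment kb per SNP (density bound).
#' @return A validated list of class `roh_call_params`.
#' @export
roh_call_params <- function(window_snps = 50L,
                            window_max_het = 1L,
                            window_max_missing = 5L,
                            snp_hit_threshold = 0.05,
                            min_snps = 100L,
                            min_length_kb = 1500,
                            max_gap_kb = 1000,
                            max_kb_per_snp = 50) {
  p <- list(window_snps = as.integer(window_snps),
            window_max_het = as.integer(window_max_het),
            window_max_missing = as.integer(window_max_missing),
            snp_hit_threshold = snp_hit_threshold,
            min_snps = as.integer(min_snps),
            min_length_kb = min_length_kb,
            max_gap_kb = max_gap_kb,
            max_kb_per_snp = max_kb_per_snp)
  if (any(unlist(p) <= 0)) abort("all ROH calling parameters must be positive")
  if (p$snp_hit_threshold > 1) abort("snp_hit_threshold must lie in (0, 1]")
  structure(p, class = "roh_call_params")
}

#' Homozygous-window predicate
#'
#' TRUE iff the window's heterozygous-call count and missing-call count are
#' both within their allowances.
#'
#' @param genotypes integer genotype codes of length `params$window_snps`.
#' @param params a [roh_call_params()].
#' @return Logical scalar.
#' @export
window_is_homozygous <- function(genotypes, params = roh_call_params()) {
  if (length(genotypes) != params$window_snps) {
    abort(sprintf("window must hold exactly %d genotypes", params$window_snps))
  }
  sum(genotypes == 1L, na.rm = TRUE) <= params$window_max_het &&
    sum(is.na(genotypes)) <= params$window_max_missing
}

# Per-SNP fraction of homozygous windows among the index windows containing
# the SNP, for one chromosome's genotype vector. Windows are the n - W + 1
# runs of W consecutive SNPs; edge SNPs sit in fewer windows.
snp_hit_fractions_chrom <- function(g, params) {
  n <- length(g)
  w <- params$window_snps
  if (n < w) return(rep(NA_real_, n))
  het <- cumsum(c(0L, as.integer(!is.na(g) & g == 1L)))
  mis <- cumsum(c(0L, as.integer(is.na(g))))
  starts <- seq_len(n - w + 1L)
  hom_win <- (het[starts + w] - het[starts]) <= params$window_max_het &
    (mis[starts + w] - mis[starts]) <= params$window_max_missing
  cum_hw <- cumsum(c(0L, as.integer(hom_win)))
  k <- seq_len(n)
  lo <- pmax(1L, k - w + 1L)            # first window containing SNP k
  hi <- pmin(k, n - w + 1L)             # last window containing SNP k
  (cum_hw[hi + 1L] - cum_hw[lo]) / (hi - lo + 1L)
}

#' Per-SNP homozygous-window coverage fractions
#'
#' For each SNP of one sample, the fraction of sliding windows containing the
#' SNP that are homozygous. Chromosomes with fewer SNPs than the window yield
#' `NA` (no calls possible there).
#'
#' @param sample_genotypes integer genotype vector aligned to `variant_map`.
#' @param variant_map variant map tibble (`chrom`, `pos_bp`), sorted.
#' @param params a [roh_call_params()].
#' @return Numeric vector of fractions, one per SNP.
#' @export
snp_hit_fractions <- function(sample_genotypes, variant_map,
                              params = roh_call_params()) {
  out <- rep(NA_real_, length(sample_genotypes))
  for (chrom in unique(variant_map$chrom)) {
    idx <- which(variant_map$chrom == chrom)
    out[idx] <- snp_hit_fractions_chrom(sample_genotypes[idx], params)
  }
  out
}

#' Call runs of homozygosity for one sample
#'
#' Marks SNPs whose homozygous-window coverage fraction reaches
#' `snp_hit_threshold`, takes maximal runs of consecutive marked SNPs per
#' chromosome, splits runs at inter-SNP gaps above `max_gap_kb`, and keeps
#' runs satisfying the SNP-count, length and density bounds. Segment spans
#' run from the first to the last member SNP (1-based inclusive).
#'
#' @inheritParams snp_hit_fractions
#' @param sample_id id recorded on the output rows.
#' @return Tibble of segments: `sample_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_kb`.
#' @export
call_roh_sample <- function(sample_genotypes, variant_map,
                            params = roh_call_params(),
                            sample_id = "sample") {
  if (is.unsorted(order(variant_map$chrom, variant_map$pos_bp))) {
    abort("variant_map must be sorted by (chrom, pos_bp)")
  }
  segs <- list()
  for (chrom in unique(variant_map$chrom)) {
    idx <- which(variant_map$chrom == chrom)
    pos <- variant_map$pos_bp[idx]
    frac <- snp_hit_fractions_chrom(sample_genotypes[idx], params)
    marked <- !is.na(frac) & frac >= params$snp_hit_threshold
    r <- rle(marked)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (run in which(r$values)) {
      lo <- starts[run]; hi <- ends[run]
      # split at gaps over max_gap_kb
      cut_after <- which(diff(pos[lo:hi]) > params$max_gap_kb * 1000)
      bounds <- c(lo - 1L, lo - 1L + cut_after, hi)
      for (b in seq_len(length(bounds) - 1L)) {
        s <- bounds[b] + 1L; e <- bounds[b + 1L]
        n_snps <- e - s + 1L
        length_kb <- (pos[e] - pos[s] + 1) / 1000
        if (n_snps >= params$min_snps &&
            length_kb > params$min_length_kb &&
            length_kb / n_snps <= params$max_kb_per_snp) {
          segs[[length(segs) + 1L]] <- tibble(
            sample_id = sample_id, chrom = chrom,
            start_bp = pos[s], end_bp = pos[e],
            n_snps = n_snps, length_kb = length_kb
          )
        }
      }
    }
  }
  if (!length(segs)) {
    return(tibble(sample_id = character(), chrom = integer(),
                  start_bp = integer(), end_bp = integer(),
                  n_snps = integer(), length_kb = numeric()))
  }
  bind_rows(segs)
}

#' Call runs of homozygosity for a cohort
#'
#' Applies [call_roh_sample()] to every sample and returns the concatenated
#' segment table ordered by (sample, chromosome, start). Every output row is
#' checked against the segment invariants (SNP count, length, density, gap).
#'
#' @param dataset a [genotype_dataset()].
#' @param params a [roh_call_params()].
#' @return Segment tibble as in [call_roh_sample()].
#' @export
call_roh_cohort <- function(dataset, params = roh_call_params()) {
  ids <- dataset$sample_sheet$sample_id
  out <- bind_rows(lapply(seq_along(ids), function(i) {
    call_roh_sample(dataset$genotypes[i, ], dataset$variant_map, params, ids[i])
  }))
  out <- arrange(out, .data$sample_id, .data$chrom, .data$start_bp)
  if (nrow(out)) {
    stopifnot(
      all(out$n_snps >= params$min_snps),
      all(out$length_kb > params$min_length_kb),
      all(out$length_kb / out$n_snps <= params$max_kb_per_snp)
    )
  }
  out
}
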