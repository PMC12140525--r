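# Sample- and variant-level quality control applied before homozygosity
# metric association: call rate, heterozygosity-based inbreeding F,
# Hardy-Weinberg exact filtering, minor-allele-frequency filtering and
# windowed LD pruning.

#' Remove samples with low genotyping call rate
#'
#' Samples whose fraction of non-missing genotypes is strictly below
#' `min_rate` (default 95%) are removed; a sample at exactly the threshold is
#' retained.
#'
#' @param dataset a [genotype_dataset()].
#' @param min_rate minimum retained call-rate fraction.
#' @return The filtered dataset; removed ids in attribute `removed_samples`.
#' @export
filter_call_rate <- function(dataset, min_rate = 0.95) {
  rate <- rowMeans(!is.na(dataset$genotypes))
  keep <- rate >= min_rate
  if (!any(keep)) abort("all samples fall below the call-rate threshold")
  if (any(!keep)) {
    inform(sprintf("call-rate filter removed %d sample(s)", sum(!keep)))
  }
  out <- subset_dataset(dataset, samples = which(keep))
  attr(out, "removed_samples") <- dataset$sample_sheet$sample_id[!keep]
  out
}

#' Heterozygosity-based inbreeding coefficient F
#'
#' Per-sample method-of-moments F from observed versus expected homozygote
#' counts: `F = (O_hom - E_hom) / (n - E_hom)` with
#' `E_hom = sum(1 - 2 p q)` over the sample's non-missing SNPs, allele
#' frequencies taken from the retained cohort. Samples with `|F| > 0.25`
#' (excess heterozygosity or homozygosity) are flagged.
#'
#' @param dataset a [genotype_dataset()].
#' @param flag_abs_f flag threshold on `|F|`.
#' @return Tibble with `sample_id`, `observed_hom`, `expected_hom`,
#'   `n_genotyped`, `f`, `flagged`.
#' @export
het_f <- function(dataset, flag_abs_f = 0.25) {
  g <- dataset$genotypes
  p <- allele2_freq(g)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) abort("F is undefined: all SNPs are monomorphic")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  nonmiss <- !is.na(g)
  exp_hom_snp <- 1 - 2 * p * (1 - p)
  expected <- as.vector(nonmiss %*% exp_hom_snp)
  observed <- rowSums(g != 1L, na.rm = TRUE)
  n_geno <- rowSums(nonmiss)
  denom <- n_geno - expected
  f <- ifelse(denom != 0, (observed - expected) / denom, NA_real_)
  tibble(
    sample_id = dataset$sample_sheet$sample_id,
    observed_hom = unname(observed), expected_hom = unname(expected),
    n_genotyped = unname(n_geno), f = unname(f),
    flagged = unname(!is.na(f) & abs(f) > flag_abs_f)
  )
}

#' Hardy-Weinberg exact test p-value
#'
#' Exact test on the heterozygote count conditional on the allele counts
#' (Wigginton, Cutler and Abecasis): the two-sided p-value sums the
#' probabilities of all heterozygote counts no more likely than the observed
#' one. Monomorphic sites return 1.
#'
#' @param n_het,n_hom1,n_hom2 genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  n_a <- 2 * n_hom1 + n_het            # rarer-or-not allele count
  n_b <- 2 * n_hom2 + n_het
  rare <- min(n_a, n_b)
  if (n == 0 || rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)  # feasible het counts share parity
  # unnormalized conditional probabilities via the standard recurrence
  logp <- numeric(length(hets))
  mid <- which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))
  logp[mid] <- 0
  for (k in seq(mid + 1, length.out = max(0, length(hets) - mid))) {
    h <- hets[k - 1]
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    logp[k] <- logp[k - 1] + log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
  }
  for (k in seq(mid - 1, length.out = max(0, mid - 1), by = -1)) {
    h <- hets[k + 1]
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    logp[k] <- logp[k + 1] + log(h * (h - 1)) - log(4 * (hom_r + 1) * (hom_c + 1))
  }
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- match(n_het, hets)
  if (is.na(obs)) abort("observed het count infeasible for the allele counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Filter variants by Hardy-Weinberg exact test
#'
#' Removes SNPs whose exact-test p-value falls below `alpha`
#' (default 1e-10, the permissive threshold used before family-branch
#' analyses). Monomorphic SNPs are retained.
#'
#' @param dataset a [genotype_dataset()].
#' @param alpha removal threshold.
#' @return Filtered dataset.
#' @export
hwe_filter <- function(dataset, alpha = 1e-10) {
  g <- dataset$genotypes
  n_het <- colSums(g == 1L, na.rm = TRUE)
  n_hom1 <- colSums(g == 0L, na.rm = TRUE)
  n_hom2 <- colSums(g == 2L, na.rm = TRUE)
  pvals <- vapply(seq_len(ncol(g)), function(j) {
    hwe_exact_pvalue(n_het[j], n_hom1[j], n_hom2[j])
  }, numeric(1))
  keep <- pvals >= alpha
  subset_dataset(dataset, variants = which(keep))
}

#' Filter variants by minor allele frequency
#'
#' Removes SNPs with minor-allele frequency strictly below `min_maf`
#' (default 5%); a SNP at exactly the threshold is retained.
#'
#' @param dataset a [genotype_dataset()].
#' @param min_maf removal threshold.
#' @return Filtered dataset.
#' @export
maf_filter <- function(dataset, min_maf = 0.05) {
  p <- allele2_freq(dataset$genotypes)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= min_maf
  subset_dataset(dataset, variants = which(keep))
}

#' Prune variants in linkage disequilibrium
#'
#' Greedy windowed pruning: within each physical window of `window_kb`
#' (anchored at successive SNPs, advancing `step` SNPs at a time), genotype
#' correlations are computed for every retained pair and, whenever
#' `r^2 > r2_max`, the SNP of the pair with the lower minor-allele frequency
#' is removed (ties: the later position). Each window is iterated to a
#' fixpoint before the anchor advances.
#'
#' @param dataset a [genotype_dataset()].
#' @param window_kb physical window size in kb.
#' @param step anchor advance in SNPs.
#' @param r2_max squared-correlation threshold.
#' @return Pruned dataset.
#' @export
ld_prune <- function(dataset, window_kb = 50, step = 5, r2_max = 0.5) {
  map <- dataset$variant_map
  g <- dataset$genotypes
  p <- allele2_freq(g)
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, nrow(map))
  for (chrom in unique(map$chrom)) {
    cidx <- which(map$chrom == chrom)
    pos <- map$pos_bp[cidx]
    anchor <- 1L
    while (anchor <= length(cidx)) {
      win <- which(pos >= pos[anchor] & pos - pos[anchor] <= window_kb * 1000)
      repeat {
        active <- win[keep[cidx[win]]]
        if (length(active) < 2) break
        removed <- FALSE
        for (a in seq_len(length(active) - 1)) {
          for (b in seq((a + 1), length(active))) {
            ja <- cidx[active[a]]; jb <- cidx[active[b]]
            if (!keep[ja] || !keep[jb]) next
            r <- suppressWarnings(
              stats::cor(g[, ja], g[, jb], use = "complete.obs"))
            if (!is.na(r) && r^2 > r2_max) {
              drop <- if (isTRUE(maf[ja] < maf[jb])) ja
                      else if (isTRUE(maf[jb] < maf[ja])) jb
                      else max(ja, jb)   # tie: later position
              keep[drop] <- FALSE
              removed <- TRUE
            }
          }
        }
        if (!removed) break
      }
      anchor <- anchor + step
    }
  }
  subset_dataset(dataset, variants = which(keep))
}
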