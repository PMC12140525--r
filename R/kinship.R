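# Relationship inference: the KING robust between-family kinship estimator,
# greedy relatedness pruning at the second-degree threshold, and principal
# components of the standardized genotype matrix.

# Pairwise KING numerator/denominator terms via indicator-matrix products,
# restricted to mutually non-missing SNPs.
king_terms <- function(genotypes) {
  het <- (genotypes == 1L); het[is.na(het)] <- FALSE
  hom1 <- (genotypes == 0L); hom1[is.na(hom1)] <- FALSE
  hom2 <- (genotypes == 2L); hom2[is.na(hom2)] <- FALSE
  nonmiss <- !is.na(genotypes)
  storage.mode(het) <- "numeric"
  storage.mode(hom1) <- "numeric"
  storage.mode(hom2) <- "numeric"
  storage.mode(nonmiss) <- "numeric"
  n_hh <- het %*% t(het)                       # both heterozygous
  n_opp <- hom1 %*% t(hom2) + hom2 %*% t(hom1) # opposite homozygotes
  het_i <- het %*% t(nonmiss)                  # [i,j]: hets of i where j typed
  list(n_hh = n_hh, n_opp = n_opp, denom = het_i + t(het_i))
}

#' KING robust kinship coefficient for all sample pairs
#'
#' Computes the between-family robust estimator
#' `phi = (N_het,het - 2 N_AA,aa) / (N_het(i) + N_het(j))` over mutually
#' non-missing SNPs, where `N_het,het` counts SNPs at which both samples are
#' heterozygous, `N_AA,aa` counts opposite homozygotes, and `N_het(.)` are the
#' per-sample heterozygote counts within the pair's shared SNPs.
#'
#' @param dataset a [genotype_dataset()].
#' @return Tibble with `sample_i`, `sample_j` (i before j in sheet order) and
#'   `phi`.
#' @export
king_kinship_all <- function(dataset) {
  ids <- dataset$sample_sheet$sample_id
  t <- king_terms(dataset$genotypes)
  phi <- (t$n_hh - 2 * t$n_opp) / t$denom
  idx <- which(upper.tri(phi), arr.ind = TRUE)
  tibble(
    sample_i = ids[idx[, 1]],
    sample_j = ids[idx[, 2]],
    phi = phi[idx]
  )
}

#' KING robust kinship for one sample pair
#'
#' @param dataset a [genotype_dataset()].
#' @param pair character vector of two sample ids.
#' @return Tibble row with `sample_i`, `sample_j`, `phi`.
#' @export
king_kinship <- function(dataset, pair) {
  rows <- match(pair, dataset$sample_sheet$sample_id)
  if (anyNA(rows) || length(rows) != 2) abort("pair must name two known samples")
  gi <- dataset$genotypes[rows[1], ]
  gj <- dataset$genotypes[rows[2], ]
  both <- !is.na(gi) & !is.na(gj)
  if (!any(both)) abort("no mutually genotyped SNPs for this pair")
  gi <- gi[both]; gj <- gj[both]
  n_hh <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  denom <- sum(gi == 1L) + sum(gj == 1L)
  if (denom == 0) abort("kinship undefined: no heterozygous SNPs in the pair")
  tibble(sample_i = pair[1], sample_j = pair[2],
         phi = (n_hh - 2 * n_opp) / denom)
}

#' Remove related samples
#'
#' Greedy pruning of pairs with kinship at or above `phi_max` (default
#' 0.0884, second-degree relatives or closer): repeatedly drop the sample in
#' the most remaining related pairs, breaking ties by dropping controls
#' before cases and then the later sample id, until no related pair remains.
#'
#' @param dataset a [genotype_dataset()].
#' @param kinships tibble from [king_kinship_all()] (or any `sample_i`,
#'   `sample_j`, `phi` table covering all related pairs).
#' @param phi_max removal threshold on kinship.
#' @return Filtered dataset; removed ids in attribute `removed_samples`.
#' @export
remove_related <- function(dataset, kinships, phi_max = KINSHIP_SECOND_DEGREE) {
  sheet <- dataset$sample_sheet
  pairs <- kinships[kinships$phi >= phi_max,
                    c("sample_i", "sample_j"), drop = FALSE]
  removed <- character()
  while (nrow(pairs) > 0) {
    deg <- table(c(pairs$sample_i, pairs$sample_j))
    cand <- names(deg)[deg == max(deg)]
    is_control <- sheet$phenotype[match(cand, sheet$sample_id)] != "case"
    if (any(is_control)) cand <- cand[is_control]
    drop <- max(cand)  # later sample id
    removed <- c(removed, drop)
    pairs <- pairs[pairs$sample_i != drop & pairs$sample_j != drop, , drop = FALSE]
  }
  if (length(removed)) {
    inform(sprintf("relatedness filter removed %d sample(s)", length(removed)))
  }
  out <- subset_dataset(dataset, samples = which(!sheet$sample_id %in% removed))
  attr(out, "removed_samples") <- removed
  out
}

#' Principal components of the genotype matrix
#'
#' Mean-imputes missing genotypes, standardizes each SNP (zero-variance SNPs
#' dropped), and returns the first `n_pcs` principal-component coordinates.
#' Sign convention: each component's largest-magnitude SNP loading is
#' positive.
#'
#' @param dataset a [genotype_dataset()], ideally MAF-filtered and LD-pruned.
#' @param n_pcs number of components.
#' @return Tibble with `sample_id` and `PC1..PCk`.
#' @export
compute_pcs <- function(dataset, n_pcs = 5) {
  ids <- dataset$sample_sheet$sample_id
  if (n_pcs == 0) return(tibble(sample_id = ids))
  g <- dataset$genotypes
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]
  s <- apply(g, 2, sd)
  keep <- !is.na(s) & s > 0
  x <- scale(g[, keep, drop = FALSE])
  sv <- svd(x, nu = min(dim(x)), nv = min(dim(x)))
  rank <- sum(sv$d > max(dim(x)) * max(sv$d) * .Machine$double.eps)
  if (n_pcs > rank) abort(sprintf("n_pcs = %d exceeds matrix rank %d", n_pcs, rank))
  scores <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  for (k in seq_len(n_pcs)) {
    v <- sv$v[, k]
    if (v[which.max(abs(v))] < 0) scores[, k] <- -scores[, k]
  }
  out <- as_tibble(setNames(as.data.frame(scores), paste0("PC", seq_len(n_pcs))))
  dplyr::bind_cols(tibble(sample_id = ids), out)
}
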