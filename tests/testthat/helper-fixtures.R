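# Shared fixtures and independent oracles.

# Minimal dataset constructor: genotypes is samples x variants; positions are
# per-chromosome bp vectors (named by chromosome number).
make_dataset <- function(genotypes, positions, phenotype = NULL, sex = NULL,
                         sample_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  if (is.null(phenotype)) phenotype <- rep("unknown", n)
  if (is.null(sex)) sex <- rep_len(c("male", "female"), n)
  map <- dplyr::bind_rows(
    tibble::tibble(chrom = integer(), pos_bp = integer()),
    lapply(names(positions), function(ch) {
      tibble::tibble(chrom = as.integer(ch), pos_bp = as.integer(positions[[ch]]))
    })
  )
  map$variant_id <- sprintf("v%d", seq_len(nrow(map)))
  map$allele1 <- "A"
  map$allele2 <- "B"
  sheet <- tibble::tibble(sample_id = sample_ids, family_id = sample_ids,
                          sex = sex, phenotype = phenotype,
                          age_at_sampling = 60, age_at_onset = NA_real_,
                          ancestry_label = "TEST")
  genotype_dataset(genotypes, sheet, map)
}

# Brute-force ROH caller: materializes every window and applies the
# het/missing, hit-fraction, run, gap, SNP-count, length and density rules
# literally, with explicit loops. Independent of the package's caller.
oracle_call_roh <- function(g, map, params = roh_call_params(),
                            sample_id = "sample") {
  w <- params$window_snps
  out <- list()
  for (chrom in unique(map$chrom)) {
    idx <- which(map$chrom == chrom)
    gc <- g[idx]
    pos <- map$pos_bp[idx]
    n <- length(gc)
    if (n < w) next
    hom_win <- logical(n - w + 1)
    for (s in seq_len(n - w + 1)) {
      win <- gc[s:(s + w - 1)]
      hom_win[s] <- sum(win == 1, na.rm = TRUE) <= params$window_max_het &&
        sum(is.na(win)) <= params$window_max_missing
    }
    marked <- logical(n)
    for (k in seq_len(n)) {
      contains <- which(seq_len(n - w + 1) <= k & seq_len(n - w + 1) + w - 1 >= k)
      marked[k] <- mean(hom_win[contains]) >= params$snp_hit_threshold
    }
    # maximal runs of marked SNPs
    k <- 1
    while (k <= n) {
      if (!marked[k]) { k <- k + 1; next }
      e <- k
      while (e < n && marked[e + 1]) e <- e + 1
      # split the run at gaps over max_gap_kb
      sub_start <- k
      for (j in k:e) {
        end_here <- j == e || (pos[j + 1] - pos[j]) > params$max_gap_kb * 1000
        if (end_here) {
          n_snps <- j - sub_start + 1
          len_kb <- (pos[j] - pos[sub_start] + 1) / 1000
          if (n_snps >= params$min_snps && len_kb > params$min_length_kb &&
              len_kb / n_snps <= params$max_kb_per_snp) {
            out[[length(out) + 1]] <- tibble::tibble(
              sample_id = sample_id, chrom = chrom,
              start_bp = pos[sub_start], end_bp = pos[j],
              n_snps = as.integer(n_snps), length_kb = len_kb
            )
          }
          sub_start <- j + 1
        }
      }
      k <- e + 1
    }
  }
  if (!length(out)) {
    return(tibble::tibble(sample_id = character(), chrom = integer(),
                          start_bp = integer(), end_bp = integer(),
                          n_snps = integer(), length_kb = numeric()))
  }
  dplyr::bind_rows(out)
}

# Newton-Raphson logistic regression, independent of stats::glm: returns
# coefficients and standard errors for design matrix X (with intercept) and
# 0/1 outcome y.
irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    H <- t(X) %*% (X * W)
    score <- t(X) %*% (y - mu)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  cov <- solve(t(X) %*% (X * mu * (1 - mu)))
  list(beta = as.vector(beta), se = sqrt(diag(cov)))
}

# Base-pair Jaccard overlap of two intervals on the same chromosome.
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  union <- (e1 - s1 + 1) + (e2 - s2 + 1) - inter
  inter / union
}

# Fraction of truth segments recovered with bp-Jaccard >= 0.8 by called
# segments of the same sample.
recovery_rate <- function(truth, called, min_jaccard = 0.8) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    cand <- called[called$sample_id == truth$sample_id[i] &
                     called$chrom == truth$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) return(FALSE)
    any(vapply(seq_len(nrow(cand)), function(j) {
      interval_jaccard(truth$start_bp[i], truth$end_bp[i],
                       cand$start_bp[j], cand$end_bp[j])
    }, numeric(1)) >= min_jaccard)
  }, logical(1))
  mean(hit)
}

# Family fixture with deterministic heterozygous flanks: three affected
# relatives (plus optional extra carriers) homozygous-identical across
# [11e6, 13.1e6] on chromosome 1 (106 SNPs: the caller's marked run keeps
# 104 after edge-window trimming), everyone else heterozygous everywhere.
family_fixture <- function(extra_carrier = NULL, n_samples = 8,
                           spacing = 20000) {
  pos <- seq(1e6, 23e6, by = spacing)
  n_snp <- length(pos)
  g <- matrix(1L, n_samples, n_snp)   # heterozygous background: no calls
  region <- pos >= 11e6 & pos <= 13.1e6
  phen <- c("case", "case", "case", rep(c("control", "case"), length.out = n_samples - 3))
  ds <- make_dataset(g, list(`1` = pos), phenotype = phen)
  truth <- list(planted_segments = tibble::tibble(
    sample_id = character(), chrom = integer(), start_bp = integer(),
    end_bp = integer(), kind = character()
  ))
  res <- plant_family_roh(ds, truth, c("S001", "S002", "S003"),
                          list(chrom = 1, start_bp = 11e6, end_bp = 13.1e6))
  if (!is.null(extra_carrier)) {
    shared <- res$dataset$genotypes[1, region]
    res$dataset$genotypes[match(extra_carrier, res$dataset$sample_sheet$sample_id),
                          region] <- shared
  }
  # kinship links only the three relatives
  kin <- tibble::tibble(sample_i = c("S001", "S001", "S002"),
                        sample_j = c("S002", "S003", "S003"),
                        phi = 0.25)
  list(dataset = res$dataset, kinships = kin)
}
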