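params <- roh_call_params()

test_that("homozygous-window predicate enforces het and missing allowances", {
  hom <- rep(0L, 50)
  expect_true(window_is_homozygous(hom, params))
  two_het <- c(rep(0L, 48), 1L, 1L)
  expect_false(window_is_homozygous(two_het, params))
  # both allowances at their maxima: still homozygous
  edge <- c(rep(2L, 44), 1L, rep(NA_integer_, 5))
  expect_true(window_is_homozygous(edge, params))
  over_miss <- c(rep(2L, 43), 1L, rep(NA_integer_, 6))
  expect_false(window_is_homozygous(over_miss, params))
  expect_error(window_is_homozygous(rep(0L, 49), params), "exactly 50")
})

test_that("hit fractions are 1 on homozygous and 0 on heterozygous chromosomes", {
  pos <- seq(1e6, by = 20000, length.out = 200)
  map <- tibble::tibble(chrom = 1L, pos_bp = as.integer(pos))
  expect_equal(snp_hit_fractions(rep(0L, 200), map, params), rep(1, 200))
  expect_equal(snp_hit_fractions(rep(1L, 200), map, params), rep(0, 200))
  # a single het still leaves every window within its allowance
  g <- rep(2L, 200); g[100] <- 1L
  frac <- snp_hit_fractions(g, map, params)
  expect_equal(frac[100], 1)
  expect_equal(frac, rep(1, 200))
  # short chromosome: undefined
  short_map <- tibble::tibble(chrom = 1L, pos_bp = as.integer(pos[1:30]))
  expect_true(all(is.na(snp_hit_fractions(rep(0L, 30), short_map, params))))
})

test_that("hit fractions match brute-force window enumeration", {
  set.seed(77)
  pos <- sort(sample.int(5e6, 150))
  map <- tibble::tibble(chrom = 1L, pos_bp = as.integer(pos))
  g <- sample(c(0L, 1L, 2L, NA), 150, replace = TRUE,
              prob = c(0.45, 0.08, 0.45, 0.02))
  frac <- snp_hit_fractions(g, map, params)
  w <- params$window_snps
  hom_win <- vapply(seq_len(150 - w + 1), function(s) {
    win <- g[s:(s + w - 1)]
    sum(win == 1, na.rm = TRUE) <= 1 && sum(is.na(win)) <= 5
  }, logical(1))
  brute <- vapply(seq_len(150), function(k) {
    starts <- max(1, k - w + 1):min(k, 150 - w + 1)
    mean(hom_win[starts])
  }, numeric(1))
  expect_equal(frac, brute)
})

test_that("caller applies SNP-count, length, gap and density rules", {
  mk <- function(pos, g) {
    list(map = tibble::tibble(chrom = 1L, pos_bp = as.integer(pos),
                              variant_id = sprintf("v%d", seq_along(pos)),
                              allele1 = "A", allele2 = "B"),
         g = g)
  }
  # 150 homozygous SNPs at 20 kb inside het flanks -> one segment. The two
  # outermost SNPs sit in only 2 of their 50 windows' homozygous set
  # (2/50 = 0.04 < 5%), so the brute-force rules keep 148 SNPs.
  pos <- seq(1e6, by = 20000, length.out = 350)
  g <- c(rep(1L, 100), rep(0L, 150), rep(1L, 100))
  fx <- mk(pos, g)
  segs <- call_roh_sample(fx$g, fx$map, params)
  expect_equal(nrow(segs), 1)
  expect_equal(as.data.frame(segs), as.data.frame(oracle_call_roh(g, fx$map, params)))
  expect_equal(segs$n_snps, 148)
  expect_equal(segs$start_bp, pos[102])
  expect_equal(segs$end_bp, pos[249])

  # 90 homozygous SNPs spanning 1.8 Mb: fails min_snps
  pos2 <- seq(1e6, by = 20000, length.out = 290)
  g2 <- c(rep(1L, 100), rep(0L, 90), rep(1L, 100))
  expect_equal(nrow(call_roh_sample(g2, mk(pos2, g2)$map, params)), 0)

  # 150-SNP run with a 1.2 Mb gap after SNP 75: split leaves halves < 100 SNPs
  pos3 <- c(seq(1e6, by = 20000, length.out = 175),
            seq(1e6 + 174 * 20000 + 1.2e6, by = 20000, length.out = 175))
  g3 <- c(rep(1L, 100), rep(0L, 150), rep(1L, 100))
  expect_equal(nrow(call_roh_sample(g3, mk(pos3, g3)$map, params)), 0)

  # 200 homozygous SNPs at 60 kb spacing: density 60 kb/SNP violates 50
  pos4 <- seq(1e6, by = 60000, length.out = 200)
  g4 <- rep(2L, 200)
  expect_equal(nrow(call_roh_sample(g4, mk(pos4, g4)$map, params)), 0)
})

test_that("caller equals the brute-force oracle on random instances", {
  set.seed(1234)
  for (rep in 1:6) {
    n <- 300
    pos <- sort(sample.int(8e6, n))
    map <- tibble::tibble(chrom = 1L, pos_bp = as.integer(pos),
                          variant_id = sprintf("v%d", 1:n),
                          allele1 = "A", allele2 = "B")
    # blocks of homozygosity embedded in noisier background
    g <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(0.4, 0.2, 0.4))
    b0 <- sample.int(n - 150, 1)
    g[b0:(b0 + 149)] <- sample(c(0L, 2L, 1L, NA), 150, replace = TRUE,
                               prob = c(0.48, 0.48, 0.015, 0.025))
    segs <- call_roh_sample(g, map, params, sample_id = "s")
    oracle <- oracle_call_roh(g, map, params, sample_id = "s")
    expect_equal(as.data.frame(segs), as.data.frame(oracle))
  }
})

test_that("cohort calling is deterministic, ordered and invariant-safe", {
  set.seed(55)
  cfg <- sim_config(n_cases = 6, n_controls = 6,
                    chrom_lengths_bp = c(`1` = 30e6, `2` = 20e6),
                    background_roh_rate = 1, het_error_rate = 0,
                    missing_rate = 0, seed = 9)
  res <- simulate_cohort(cfg)
  segs <- call_roh_cohort(res$dataset)
  expect_identical(segs, call_roh_cohort(res$dataset))
  expect_false(is.unsorted(order(segs$sample_id, segs$chrom, segs$start_bp)))
  expect_true(all(segs$n_snps >= 100))
  expect_true(all(segs$length_kb > 1500))
  expect_true(all(segs$length_kb / segs$n_snps <= 50))
  # all-het cohort yields nothing
  het <- res$dataset
  het$genotypes[] <- 1L
  expect_equal(nrow(call_roh_cohort(het)), 0)
})

test_that("a planted segment in an otherwise clean sample is called", {
  set.seed(60)
  cfg <- sim_config(n_cases = 2, n_controls = 2,
                    chrom_lengths_bp = c(`1` = 30e6),
                    background_roh_rate = 0, het_error_rate = 0,
                    missing_rate = 0, seed = 3)
  res <- simulate_cohort(cfg)
  ds <- res$dataset
  truth <- res$truth
  map <- ds$variant_map
  ds$genotypes <- rohmap:::plant_homozygous(
    ds$genotypes, map, rep(0.3, nrow(map)), 1, 1L, 5e6, 8e6)
  segs <- call_roh_cohort(ds)
  expect_equal(unique(segs$sample_id), "S0001")
  expect_equal(nrow(segs), 1)
  expect_gte(interval_jaccard(5e6, 8e6, segs$start_bp, segs$end_bp), 0.9)
})
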