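seg <- function(id, chrom, start, end) {
  tibble::tibble(sample_id = id, chrom = as.integer(chrom),
                 start_bp = as.integer(start), end_bp = as.integer(end),
                 n_snps = 150L, length_kb = (end - start + 1) / 1000)
}

test_that("pooling intersects overlapping spans and partitions segments", {
  # three segments sharing a 500 kb core
  segs <- dplyr::bind_rows(
    seg("a", 1, 1.0e6, 4.0e6),
    seg("b", 1, 2.0e6, 4.5e6),
    seg("c", 1, 3.5e6, 6.0e6)
  )
  pools <- build_pools(segs)
  expect_equal(nrow(pools), 1)
  expect_equal(pools$consensus_start_bp, 3.5e6)
  expect_equal(pools$consensus_end_bp, 4.0e6)
  expect_equal(pools$consensus_kb, 500.001)
  # disjoint segments form separate pools
  segs2 <- dplyr::bind_rows(seg("a", 1, 1e6, 3e6), seg("b", 1, 5e6, 7e6))
  expect_equal(nrow(build_pools(segs2)), 2)
  # chain a-b-c with a and c disjoint: c is left for its own pool
  chain <- dplyr::bind_rows(
    seg("a", 1, 1.0e6, 4.0e6),   # longest: seed
    seg("b", 1, 3.8e6, 6.0e6),
    seg("c", 1, 4.5e6, 6.5e6)    # overlaps b but not a
  )
  pc <- build_pools(chain)
  expect_equal(nrow(pc), 2)
  expect_equal(sum(vapply(pc$members, nrow, integer(1))), nrow(chain))
  # partition property on random segments
  set.seed(42)
  rand <- dplyr::bind_rows(lapply(1:60, function(i) {
    s <- sample.int(3e7, 1)
    seg(sprintf("s%02d", i %% 10), sample(1:3, 1), s, s + sample.int(4e6, 1))
  }))
  pr <- build_pools(rand)
  expect_equal(sum(vapply(pr$members, nrow, integer(1))), nrow(rand))
})

test_that("pool filtering is strict on both criteria and idempotent", {
  map <- tibble::tibble(chrom = 1L,
                        pos_bp = as.integer(seq(1e6, 9e6, by = 1000)))
  segs <- dplyr::bind_rows(
    seg("a", 1, 2e6, 2.099e6),   # 99 kb consensus
    seg("b", 1, 2e6, 2.099e6),
    seg("c", 1, 4e6, 4.15e6),    # 150 kb, 151 SNPs at 1 kb spacing
    seg("d", 1, 4e6, 4.15e6)
  )
  pools <- build_pools(segs, map)
  out <- filter_pools(pools)
  expect_equal(nrow(out), 1)
  expect_equal(out$consensus_start_bp, 4e6)
  expect_equal(filter_pools(out), out)
  # sparse consensus: 150 kb but few SNPs
  sparse_map <- tibble::tibble(chrom = 1L,
                               pos_bp = as.integer(seq(1e6, 9e6, by = 2000)))
  pools2 <- build_pools(segs[3:4, ], sparse_map)
  expect_equal(nrow(filter_pools(pools2)), 0)  # 76 SNPs <= 100
})

test_that("case exclusivity and carrier counts come from consensus overlap", {
  sheet <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                          phenotype = c("case", "case", "case", "control"))
  segs <- dplyr::bind_rows(
    seg("a", 1, 1e6, 3e6), seg("b", 1, 1.5e6, 3.5e6), seg("c", 1, 1e6, 2.8e6),
    seg("d", 2, 1e6, 3e6)
  )
  pools <- flag_case_exclusive(build_pools(segs), segs, sheet)
  p1 <- pools[pools$chrom == 1, ]
  expect_equal(p1$case_carriers, 3L)
  expect_equal(p1$control_carriers, 0L)
  expect_true(p1$case_exclusive)
  p2 <- pools[pools$chrom == 2, ]
  expect_equal(p2$case_carriers, 0L)
  expect_false(p2$case_exclusive)
  # a control segment overlapping the chrom-1 consensus breaks exclusivity
  segs3 <- dplyr::bind_rows(segs, seg("d", 1, 2e6, 2.2e6))
  pools3 <- flag_case_exclusive(build_pools(segs3), segs3, sheet)
  p13 <- pools3[pools3$chrom == 1 & pools3$case_carriers == 3, ]
  expect_equal(p13$control_carriers, 1L)
  expect_false(p13$case_exclusive)
})

test_that("equal-proportions test matches its closed form and chi-square", {
  pools <- tibble::tibble(pool_id = "p1", case_carriers = 20L,
                          control_carriers = 5L)
  out <- test_pool_enrichment(pools, 100, 100)
  expect_equal(out$statistic, 3.2071, tolerance = 1e-4)
  expect_equal(out$p_value, 1.34e-3, tolerance = 1e-2)
  # equal proportions: z = 0, p = 1
  eq <- test_pool_enrichment(tibble::tibble(pool_id = "p", case_carriers = 10L,
                                            control_carriers = 10L), 100, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # degenerate: no carriers at all
  none <- test_pool_enrichment(tibble::tibble(pool_id = "p", case_carriers = 0L,
                                              control_carriers = 0L), 50, 50)
  expect_equal(none$p_value, 1)
  # z^2 equals the continuity-uncorrected chi-square on random tables
  set.seed(7)
  for (i in 1:100) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    x1 <- rbinom(1, n1, 0.3); x2 <- rbinom(1, n2, 0.3)
    if (x1 + x2 == 0 || x1 + x2 == n1 + n2) next
    z <- test_pool_enrichment(
      tibble::tibble(pool_id = "p", case_carriers = x1, control_carriers = x2),
      n1, n2)$statistic
    chi <- suppressWarnings(
      stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$statistic)
    expect_equal(z^2, unname(chi), tolerance = 1e-8)
  }
})

test_that("the enrichment test keeps its nominal type-I error", {
  set.seed(9)
  reject <- replicate(1000, {
    x1 <- rbinom(1, 200, 0.1)
    x2 <- rbinom(1, 200, 0.1)
    test_pool_enrichment(
      tibble::tibble(pool_id = "p", case_carriers = x1, control_carriers = x2),
      200, 200)$p_value < 0.05
  })
  expect_lt(abs(mean(reject) - 0.05), 0.015)
})

test_that("gene-region intersection honors the 1 Mb flank arithmetic", {
  regions <- tibble::tibble(name = "G", chrom = 1L,
                            start_bp = 10000000L, end_bp = 10050000L,
                            category = "risk_locus")
  # window [9.0, 11.05] Mb; segment ending 9.2 Mb overlaps by 200,001 bp
  items <- dplyr::bind_rows(
    seg("a", 1, 8.0e6, 9.2e6),
    seg("b", 1, 8.0e6, 8.9e6),
    seg("c", 2, 9.5e6, 10.5e6)
  )
  ov <- intersect_gene_regions(items, regions)
  expect_equal(nrow(ov), 1)
  expect_match(ov$item_id, "^a:")
  expect_equal(ov$overlap_bp, 200001)
  # zero flank reduces to plain overlap
  expect_equal(nrow(intersect_gene_regions(items, regions, flank_bp = 0)), 0)
  direct <- dplyr::bind_rows(items, seg("d", 1, 10.04e6, 10.2e6))
  expect_equal(nrow(intersect_gene_regions(direct, regions, flank_bp = 0)), 1)
  # pools are accepted via consensus coordinates
  pools <- build_pools(dplyr::bind_rows(seg("a", 1, 9.1e6, 9.3e6),
                                        seg("b", 1, 9.15e6, 9.35e6)))
  ovp <- intersect_gene_regions(pools, regions)
  expect_equal(ovp$item_id, pools$pool_id)
})

test_that("family segregation requires matching, exclusivity and kinship", {
  set.seed(12)
  fx <- family_fixture()
  segs <- call_roh_cohort(fx$dataset)
  pools <- flag_case_exclusive(
    filter_pools(build_pools(segs, fx$dataset$variant_map)),
    segs, fx$dataset$sample_sheet)
  hits <- family_segregation(pools, fx$dataset, fx$kinships)
  expect_equal(nrow(hits), 1)
  expect_equal(sort(hits$member_ids[[1]]), c("S001", "S002", "S003"))
  expect_equal(hits$min_pairwise_match, 1.0)

  # a control sharing the consensus suppresses the hit
  fx2 <- family_fixture(extra_carrier = "S004")   # S004 is a control
  segs2 <- call_roh_cohort(fx2$dataset)
  pools2 <- flag_case_exclusive(
    filter_pools(build_pools(segs2, fx2$dataset$variant_map)),
    segs2, fx2$dataset$sample_sheet)
  expect_equal(nrow(family_segregation(pools2, fx2$dataset, fx2$kinships)), 0)

  # two affecteds homozygous for opposite alleles: match 0, no hit
  fx3 <- family_fixture()
  region <- which(fx3$dataset$variant_map$pos_bp >= 11e6 &
                    fx3$dataset$variant_map$pos_bp <= 13e6)
  fx3$dataset$genotypes[2, region] <- 2L - fx3$dataset$genotypes[2, region]
  segs3 <- call_roh_cohort(fx3$dataset)
  pools3 <- flag_case_exclusive(
    filter_pools(build_pools(segs3, fx3$dataset$variant_map)),
    segs3, fx3$dataset$sample_sheet)
  expect_equal(nrow(family_segregation(pools3, fx3$dataset, fx3$kinships)), 0)
})
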