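test_that("call-rate filter removes strictly below threshold", {
  set.seed(10)
  g <- matrix(sample(0:2, 3 * 100, replace = TRUE), 3, 100)
  g[1, 1:6] <- NA   # 94% call rate: removed
  g[2, 1:5] <- NA   # exactly 95%: retained
  ds <- make_dataset(g, list(`1` = sort(sample.int(1e7, 100))))
  out <- suppressMessages(filter_call_rate(ds))
  expect_equal(out$sample_sheet$sample_id, c("S002", "S003"))
  expect_equal(attr(out, "removed_samples"), "S001")
  # idempotent
  expect_equal(suppressMessages(filter_call_rate(out))$sample_sheet$sample_id,
               out$sample_sheet$sample_id)
  # all below threshold errors
  g2 <- matrix(NA_integer_, 2, 10)
  ds2 <- make_dataset(g2, list(`1` = 1:10))
  expect_error(filter_call_rate(ds2), "all samples")
})

test_that("heterozygosity F matches its defining formula", {
  # 2 SNPs at p = 0.5 via two samples hom1/hom2; third sample het at both:
  # expected_hom = 1, observed = 0, F = (0 - 1)/(2 - 1) = -1
  g <- rbind(c(0L, 0L), c(2L, 2L), c(1L, 1L))
  ds <- make_dataset(g, list(`1` = c(1000, 2000)))
  f <- het_f(ds)
  expect_equal(f$expected_hom[3], 1)
  expect_equal(f$observed_hom[3], 0)
  expect_equal(f$f[3], -1)
  expect_true(f$flagged[3])
  # fully homozygous sample: F = 1
  expect_equal(f$f[1], 1)
  expect_equal(f$f[2], 1)
  # monomorphic-only dataset is undefined
  mono <- make_dataset(rbind(c(0L, 0L), c(0L, 0L)), list(`1` = c(1, 2)))
  expect_error(het_f(mono), "monomorphic")
})

test_that("under HWE simulation F is near zero in expectation", {
  set.seed(99)
  m <- 5000
  n <- 100   # frequencies estimated in-sample bias F by about -1/(2n)
  p <- runif(m, 0.1, 0.5)
  g <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  ds <- make_dataset(g, list(`1` = seq_len(m) * 100))
  expect_lt(abs(mean(het_f(ds)$f)), 0.02)
})

test_that("Hardy-Weinberg exact test matches direct enumeration", {
  # direct enumeration oracle: hypergeometric-type conditional distribution
  enum_p <- function(n_het, n_hom1, n_hom2) {
    n <- n_het + n_hom1 + n_hom2
    na <- 2 * n_hom1 + n_het
    hets <- seq(min(na, 2 * n - na) %% 2, min(na, 2 * n - na), by = 2)
    logpr <- vapply(hets, function(h) {
      h1 <- (na - h) / 2
      h2 <- n - h - h1
      lfactorial(n) - lfactorial(h1) - lfactorial(h) - lfactorial(h2) +
        h * log(2) + lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n)
    }, numeric(1))
    pr <- exp(logpr - max(logpr)); pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(n_het, hets)] * (1 + 1e-12)])
  }
  expect_equal(hwe_exact_pvalue(50, 25, 25), 1)
  expect_equal(hwe_exact_pvalue(0, 50, 50), enum_p(0, 50, 50), tolerance = 1e-10)
  expect_lt(hwe_exact_pvalue(0, 50, 50), 1e-10)
  for (case in list(c(10, 5, 8), c(3, 40, 2), c(21, 10, 11), c(2, 2, 2))) {
    expect_equal(hwe_exact_pvalue(case[1], case[2], case[3]),
                 enum_p(case[1], case[2], case[3]), tolerance = 1e-10)
  }
  # monomorphic degenerate
  expect_equal(hwe_exact_pvalue(0, 30, 0), 1)
})

test_that("HWE filter removes gross violations and keeps monomorphic SNPs", {
  g <- cbind(
    c(rep(0L, 25), rep(1L, 50), rep(2L, 25)),  # perfect HWE
    c(rep(0L, 50), rep(2L, 50)),               # no hets: p << 1e-10
    rep(0L, 100)                               # monomorphic
  )
  ds <- make_dataset(g, list(`1` = c(1000, 2000, 3000)))
  out <- hwe_filter(ds)
  expect_equal(out$variant_map$pos_bp, c(1000L, 3000L))
  expect_equal(hwe_filter(out)$variant_map, out$variant_map)  # idempotent
})

test_that("MAF filter removes strictly below threshold", {
  # 10 samples: col1 MAF 0.05 (1 het), col2 MAF 0.04 impossible with n=10,
  # use 0 carriers (MAF 0) and col3 common
  g <- cbind(c(1L, rep(0L, 9)), rep(0L, 10),
             c(rep(0L, 5), rep(2L, 5)))
  ds <- make_dataset(g, list(`1` = c(1000, 2000, 3000)))
  out <- maf_filter(ds)
  expect_equal(out$variant_map$pos_bp, c(1000L, 3000L))
  expect_equal(maf_filter(out)$variant_map, out$variant_map)
})

test_that("LD pruning drops duplicated SNPs inside the window only", {
  set.seed(4)
  base <- sample(0:2, 200, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  # duplicates 10 kb apart -> r2 = 1 -> one removed
  g <- cbind(base, base)
  ds <- make_dataset(g, list(`1` = c(100000, 110000)))
  out <- ld_prune(ds)
  expect_equal(nrow(out$variant_map), 1)
  # duplicates 60 kb apart -> outside the 50 kb window -> both kept
  ds2 <- make_dataset(g, list(`1` = c(100000, 160000)))
  expect_equal(nrow(ld_prune(ds2)$variant_map), 2)
  # independent SNPs under HWE survive
  m <- 60
  p <- runif(m, 0.2, 0.5)
  g3 <- matrix(rbinom(500 * m, 2, rep(p, each = 500)), 500, m)
  ds3 <- make_dataset(g3, list(`1` = seq_len(m) * 10000))
  expect_equal(nrow(ld_prune(ds3)$variant_map), m)
})

test_that("KING kinship recovers duplicates, unrelateds and parent-offspring", {
  set.seed(11)
  m <- 5000
  p <- runif(m, 0.1, 0.5)
  ga <- rbinom(m, 2, p)
  # duplicate -> phi = 0.5
  ds <- make_dataset(rbind(ga, ga), list(`1` = seq_len(m) * 100))
  expect_equal(king_kinship(ds, c("S001", "S002"))$phi, 0.5)
  # unrelated HWE pair -> phi near 0
  n <- 30
  g <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  dsu <- make_dataset(g, list(`1` = seq_len(m) * 100))
  kin <- king_kinship_all(dsu)
  expect_lt(abs(mean(kin$phi)), 0.02)
  # parent-offspring by gamete dropping: child allele1 from parent
  parent <- rbinom(m, 2, p)
  from_parent <- rbinom(m, 1, parent / 2)
  child <- from_parent + rbinom(m, 1, p)
  dsp <- make_dataset(rbind(parent, child), list(`1` = seq_len(m) * 100))
  phi_po <- king_kinship(dsp, c("S001", "S002"))$phi
  expect_lt(abs(phi_po - 0.25), 0.03)
  # symmetric in pair order
  expect_equal(phi_po, king_kinship(dsp, c("S002", "S001"))$phi)
})

test_that("relatedness removal is greedy with case-preserving ties", {
  g <- matrix(sample(0:2, 4 * 50, replace = TRUE), 4, 50)
  ds <- make_dataset(g, list(`1` = seq_len(50) * 1000),
                     phenotype = c("case", "control", "case", "case"))
  # one related case-control pair: control dropped
  kin <- tibble::tibble(sample_i = "S001", sample_j = "S002", phi = 0.25)
  out <- suppressMessages(remove_related(ds, kin))
  expect_equal(attr(out, "removed_samples"), "S002")
  # below-threshold pair: both kept
  kin2 <- tibble::tibble(sample_i = "S001", sample_j = "S002", phi = 0.08)
  expect_equal(nrow(remove_related(ds, kin2)$genotypes), 4)
  # triangle of three: exactly one survivor among the three
  kin3 <- tibble::tibble(sample_i = c("S001", "S001", "S003"),
                         sample_j = c("S003", "S004", "S004"),
                         phi = 0.3)
  out3 <- suppressMessages(remove_related(ds, kin3))
  expect_length(attr(out3, "removed_samples"), 2)
  expect_length(intersect(c("S001", "S003", "S004"),
                          out3$sample_sheet$sample_id), 1)
})

test_that("principal components separate simulated populations", {
  set.seed(21)
  m <- 300
  p1 <- runif(m, 0.05, 0.95)
  shift <- ifelse(p1 < 0.5, 0.4, -0.4)
  p2 <- p1 + shift
  g <- rbind(
    matrix(rbinom(25 * m, 2, rep(p1, each = 25)), 25, m),
    matrix(rbinom(25 * m, 2, rep(p2, each = 25)), 25, m)
  )
  ds <- make_dataset(g, list(`1` = seq_len(m) * 1000))
  pcs <- compute_pcs(ds, n_pcs = 2)
  pc1 <- pcs$PC1
  lab <- rep(1:2, each = 25)
  # silhouette of the two clusters on PC1
  sil <- vapply(seq_along(pc1), function(i) {
    a <- mean(abs(pc1[i] - pc1[lab == lab[i]][-match(i, which(lab == lab[i]))]))
    b <- mean(abs(pc1[i] - pc1[lab != lab[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)
  # duplicate rows get identical coordinates
  g2 <- rbind(g[1, ], g[1, ], g[2:10, ])
  ds2 <- make_dataset(g2, list(`1` = seq_len(m) * 1000))
  pcs2 <- compute_pcs(ds2, n_pcs = 2)
  expect_equal(pcs2$PC1[1], pcs2$PC1[2])
  expect_equal(pcs2$PC2[1], pcs2$PC2[2])
  # n_pcs = 0 and rank guard
  expect_equal(names(compute_pcs(ds, 0)), "sample_id")
  small <- make_dataset(g[1:3, ], list(`1` = seq_len(m) * 1000))
  expect_error(compute_pcs(small, n_pcs = 5), "rank")
})
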