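# Homozygosity mapping: consensus ROH pools across individuals,
# case-exclusive and case-enriched pools, the equal-proportions enrichment
# test, gene-region intersection, and family-segregating ROH detection.

#' Group overlapping ROH segments into consensus pools
#'
#' Greedy longest-seed pooling: the longest unassigned segment seeds a pool;
#' every unassigned segment on the same chromosome whose span overlaps the
#' pool's current consensus joins it, the consensus shrinking to the
#' intersection of all member spans; the scan repeats until no segment joins,
#' then the next seed starts. Each segment lands in exactly one pool, and
#' every member span contains the whole consensus. Ties between equal-length
#' seeds go to the earlier (chrom, start).
#'
#' @param segments segment tibble from [call_roh_cohort()].
#' @param variant_map optional variant map; when supplied,
#'   `consensus_n_snps` counts array SNPs inside each consensus.
#' @return Pool tibble: `pool_id`, `chrom`, `consensus_start_bp`,
#'   `consensus_end_bp`, `consensus_kb`, `consensus_n_snps`, `n_members`,
#'   and a `members` list-column of member segment tibbles.
#' @export
build_pools <- function(segments, variant_map = NULL) {
  empty <- tibble(pool_id = character(), chrom = integer(),
                  consensus_start_bp = integer(), consensus_end_bp = integer(),
                  consensus_kb = numeric(), consensus_n_snps = integer(),
                  n_members = integer(), members = list())
  if (nrow(segments) == 0) return(empty)
  ord <- order(-segments$length_kb, segments$chrom, segments$start_bp)
  segs <- segments[ord, , drop = FALSE]
  assigned <- rep(FALSE, nrow(segs))
  pools <- list()
  while (!all(assigned)) {
    seed <- which(!assigned)[1]
    assigned[seed] <- TRUE
    members <- seed
    cs <- segs$start_bp[seed]; ce <- segs$end_bp[seed]
    chrom <- segs$chrom[seed]
    repeat {
      cand <- which(!assigned & segs$chrom == chrom &
                      segs$start_bp <= ce & segs$end_bp >= cs)
      if (!length(cand)) break
      j <- cand[1]
      assigned[j] <- TRUE
      members <- c(members, j)
      cs <- max(cs, segs$start_bp[j])
      ce <- min(ce, segs$end_bp[j])
    }
    pools[[length(pools) + 1L]] <- list(
      chrom = chrom, cs = cs, ce = ce, members = segs[members, , drop = FALSE]
    )
  }
  out <- bind_rows(lapply(pools, function(p) {
    tibble(chrom = p$chrom, consensus_start_bp = p$cs, consensus_end_bp = p$ce,
           consensus_kb = (p$ce - p$cs + 1) / 1000,
           n_members = nrow(p$members), members = list(p$members))
  }))
  out <- arrange(out, .data$chrom, .data$consensus_start_bp)
  out$pool_id <- sprintf("pool_%03d", seq_len(nrow(out)))
  if (!is.null(variant_map)) {
    out$consensus_n_snps <- vapply(seq_len(nrow(out)), function(i) {
      sum(variant_map$chrom == out$chrom[i] &
            variant_map$pos_bp >= out$consensus_start_bp[i] &
            variant_map$pos_bp <= out$consensus_end_bp[i])
    }, integer(1))
  } else {
    out$consensus_n_snps <- NA_integer_
  }
  select(out, "pool_id", "chrom", "consensus_start_bp", "consensus_end_bp",
         "consensus_kb", "consensus_n_snps", "n_members", "members")
}

#' Filter consensus pools by size
#'
#' Retains pools whose consensus is strictly longer than `min_kb` and holds
#' strictly more than `min_snps` array SNPs — the guard against sparse-marker
#' false positives.
#'
#' @param pools pool tibble from [build_pools()].
#' @param min_kb,min_snps strict lower bounds.
#' @return Filtered pool tibble.
#' @export
filter_pools <- function(pools, min_kb = 100, min_snps = 100) {
  filter(pools, .data$consensus_kb > min_kb, .data$consensus_n_snps > min_snps)
}

# Sample ids carrying >= 1 segment overlapping the consensus of each pool.
pool_carriers <- function(pools, segments) {
  lapply(seq_len(nrow(pools)), function(i) {
    hit <- segments$chrom == pools$chrom[i] &
      segments$start_bp <= pools$consensus_end_bp[i] &
      segments$end_bp >= pools$consensus_start_bp[i]
    unique(segments$sample_id[hit])
  })
}

#' Flag case-exclusive pools and count carriers
#'
#' A carrier is a sample with at least one segment overlapping the pool
#' consensus. A pool is case-exclusive when it has no control carrier.
#'
#' @param pools pool tibble.
#' @param segments the full segment tibble used for pooling.
#' @param sample_sheet sample sheet with `phenotype`.
#' @return Pools with `case_carriers`, `control_carriers`, `case_exclusive`
#'   and a `carriers` list-column.
#' @export
flag_case_exclusive <- function(pools, segments, sample_sheet) {
  carriers <- pool_carriers(pools, segments)
  status <- setNames(sample_sheet$phenotype, sample_sheet$sample_id)
  pools$carriers <- carriers
  pools$case_carriers <- vapply(carriers, function(ids) {
    sum(status[ids] == "case", na.rm = TRUE)
  }, integer(1))
  pools$control_carriers <- vapply(carriers, function(ids) {
    sum(status[ids] == "control", na.rm = TRUE)
  }, integer(1))
  pools$case_exclusive <- pools$control_carriers == 0L
  pools
}

# Two-sided pooled two-proportion z test without continuity correction.
two_prop_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  if (is.na(se) || se == 0) return(list(z = 0, p = 1))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Equal-proportions enrichment test per pool
#'
#' Tests whether each pool's carrier proportion differs between cases and
#' controls with a two-sided pooled two-proportion z-test (no continuity
#' correction): `z = (p1 - p2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))`. The
#' Bonferroni flag divides `alpha` by the number of pools tested. Pools with
#' no carriers at all are degenerate (`p = 1`).
#'
#' @param pools pool tibble with carrier counts from [flag_case_exclusive()].
#' @param n_cases,n_controls group sizes.
#' @param alpha family-wise error rate.
#' @return Pools with `case_freq`, `control_freq`, `statistic`, `p_value`,
#'   `passes_bonferroni`.
#' @export
test_pool_enrichment <- function(pools, n_cases, n_controls, alpha = 0.05) {
  if (n_cases < 1 || n_controls < 1) abort("need at least one case and one control")
  res <- lapply(seq_len(nrow(pools)), function(i) {
    two_prop_z(pools$case_carriers[i], n_cases,
               pools$control_carriers[i], n_controls)
  })
  pools$case_freq <- pools$case_carriers / n_cases
  pools$control_freq <- pools$control_carriers / n_controls
  pools$statistic <- vapply(res, `[[`, numeric(1), "z")
  pools$p_value <- vapply(res, `[[`, numeric(1), "p")
  thr <- bonferroni_threshold(alpha, max(nrow(pools), 1))
  pools$passes_bonferroni <- pools$p_value < thr
  pools
}

#' Intersect pools or segments with gene regions
#'
#' Reports every (item, region) pair whose intervals overlap once each region
#' is expanded by `flank_bp` (default 1 Mb, the window used around known
#' genes and GWAS hits). Accepts either a pool tibble (consensus coordinates)
#' or a segment tibble.
#'
#' @param items pool or segment tibble.
#' @param regions gene-region tibble from [read_gene_regions()].
#' @param flank_bp flank on each region side.
#' @return Tibble with `item_id`, `region_name`, `category`, `overlap_bp`.
#' @export
intersect_gene_regions <- function(items, regions, flank_bp = 1e6) {
  if ("consensus_start_bp" %in% names(items)) {
    id <- items$pool_id; s <- items$consensus_start_bp; e <- items$consensus_end_bp
  } else {
    id <- sprintf("%s:%d:%d", items$sample_id, items$chrom, items$start_bp)
    s <- items$start_bp; e <- items$end_bp
  }
  chrom <- items$chrom
  rows <- list()
  for (k in seq_len(nrow(regions))) {
    lo <- regions$start_bp[k] - flank_bp
    hi <- regions$end_bp[k] + flank_bp
    hit <- which(chrom == regions$chrom[k] & s <= hi & e >= lo)
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- tibble(
        item_id = id[hit],
        region_name = regions$name[k],
        category = regions$category[k],
        overlap_bp = pmin(e[hit], hi) - pmax(s[hit], lo) + 1
      )
    }
  }
  if (!length(rows)) {
    return(tibble(item_id = character(), region_name = character(),
                  category = character(), overlap_bp = numeric()))
  }
  bind_rows(rows)
}

#' Detect family-segregating ROH pools
#'
#' Families are the connected components of the kinship graph at
#' `phi >= phi_min` (second-degree or closer). For each family with at least
#' two affected carriers of a pool, the pairwise allelic match (fraction of
#' identical genotype codes over mutually non-missing consensus SNPs) is
#' computed for every affected pair; the pool is reported when every pair
#' matches at or above `match_threshold` and no control carries the
#' consensus.
#'
#' @param pools pool tibble with carriers from [flag_case_exclusive()].
#' @param dataset the [genotype_dataset()] the segments were called from.
#' @param kinships kinship tibble (`sample_i`, `sample_j`, `phi`).
#' @param match_threshold minimum pairwise allelic match.
#' @param phi_min kinship threshold defining families.
#' @return Tibble with `family_id`, `pool_id`, `member_ids` (list),
#'   `min_pairwise_match`.
#' @export
family_segregation <- function(pools, dataset, kinships,
                               match_threshold = 0.95,
                               phi_min = KINSHIP_SECOND_DEGREE) {
  empty <- tibble(family_id = character(), pool_id = character(),
                  member_ids = list(), min_pairwise_match = numeric())
  rel <- kinships[kinships$phi >= phi_min, , drop = FALSE]
  if (nrow(rel) == 0 || nrow(pools) == 0) return(empty)
  gr <- igraph::graph_from_data_frame(rel[c("sample_i", "sample_j")],
                                      directed = FALSE)
  comp <- igraph::components(gr)$membership
  fam_of <- setNames(sprintf("fam_%02d", comp), names(comp))
  sheet <- dataset$sample_sheet
  status <- setNames(sheet$phenotype, sheet$sample_id)
  map <- dataset$variant_map
  hits <- list()
  for (i in seq_len(nrow(pools))) {
    carriers <- pools$carriers[[i]]
    if (any(status[carriers] == "control", na.rm = TRUE)) next
    aff <- carriers[status[carriers] == "case" & carriers %in% names(fam_of)]
    if (length(aff) < 2) next
    snp_idx <- which(map$chrom == pools$chrom[i] &
                       map$pos_bp >= pools$consensus_start_bp[i] &
                       map$pos_bp <= pools$consensus_end_bp[i])
    for (fam in unique(fam_of[aff])) {
      members <- aff[fam_of[aff] == fam]
      if (length(members) < 2) next
      matches <- c()
      ok <- TRUE
      prs <- utils::combn(members, 2, simplify = FALSE)
      for (pr in prs) {
        gi <- dataset$genotypes[pr[1], snp_idx]
        gj <- dataset$genotypes[pr[2], snp_idx]
        both <- !is.na(gi) & !is.na(gj)
        if (!any(both)) {
          warn(sprintf("pool %s: pair %s-%s has no mutually genotyped consensus SNPs",
                       pools$pool_id[i], pr[1], pr[2]))
          next
        }
        matches <- c(matches, mean(gi[both] == gj[both]))
      }
      if (!length(matches) || any(matches < match_threshold)) ok <- FALSE
      if (ok) {
        hits[[length(hits) + 1L]] <- tibble(
          family_id = fam, pool_id = pools$pool_id[i],
          member_ids = list(members), min_pairwise_match = min(matches)
        )
      }
    }
  }
  if (!length(hits)) return(empty)
  bind_rows(hits)
}
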