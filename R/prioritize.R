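# Rare homozygous variant prioritization inside mapped ROH pools: filter an
# annotated (VEP-style) variant table to rare, consequence-relevant variants
# carried homozygous, and rank candidates for reporting.

#' Default consequence set for prioritization
#'
#' Protein-truncating, splice-disrupting, missense and in-frame consequences
#' — the classes retained when filtering on variant consequence.
#' @export
DEFAULT_CONSEQUENCES <- c(
  "stop_gained", "stop_lost", "start_lost", "frameshift_variant",
  "splice_donor_variant", "splice_acceptor_variant",
  "missense_variant", "inframe_insertion", "inframe_deletion"
)

#' Read an annotated-variant table
#'
#' Reads a VEP-style TSV with columns `chrom`, `pos_bp`, `ref`, `alt`,
#' `gene`, `consequence`, `max_credible_af` plus per-sample genotype columns
#' prefixed `GT_` (codes 0/1/2, alternate-allele dosage). Alternative column
#' names can be mapped with `col_map` (a named vector `internal = file`).
#' Extra columns (e.g. in-silico scores) are carried through untouched.
#'
#' @param path TSV path.
#' @param col_map optional named character vector renaming file columns.
#' @return Tibble with a `genotypes` list-column of named dosage vectors.
#' @export
read_annotated_variants <- function(path, col_map = NULL) {
  df <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE))
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      names(df)[names(df) == col_map[[nm]]] <- nm
    }
  }
  req <- c("chrom", "pos_bp", "ref", "alt", "gene", "consequence", "max_credible_af")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste("variant table missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  gt_cols <- grep("^GT_", names(df), value = TRUE)
  ids <- sub("^GT_", "", gt_cols)
  df$genotypes <- lapply(seq_len(nrow(df)), function(i) {
    setNames(as.integer(df[i, gt_cols]), ids)
  })
  df[gt_cols] <- NULL
  df$chrom <- as.integer(df$chrom)
  df$pos_bp <- as.integer(df$pos_bp)
  df
}

# TRUE for consequence strings (possibly "&"-joined) with any term in the set.
consequence_in_set <- function(consequence, consequence_set) {
  vapply(strsplit(consequence, "[&,;]"), function(terms) {
    any(trimws(terms) %in% consequence_set)
  }, logical(1))
}

#' Prioritize variants inside ROH pools
#'
#' Retains variants that (1) lie inside a supplied pool consensus interval,
#' (2) have maximum credible ancestry-group allele frequency at most
#' `af_max` (inclusive), (3) carry a consequence in `consequence_set`, and
#' (4) are homozygous for the alternate allele in at least one carrier.
#' Variants outside every pool are excluded with a logged count.
#'
#' @param variants tibble from [read_annotated_variants()].
#' @param pools pool tibble from [build_pools()].
#' @param af_max allele-frequency ceiling (inclusive).
#' @param consequence_set retained consequence terms.
#' @return Filtered variant tibble with an added `n_hom_carriers` column.
#' @export
prioritize_variants <- function(variants, pools, af_max = 0.01,
                                consequence_set = DEFAULT_CONSEQUENCES) {
  if (nrow(variants) == 0) return(mutate(variants, n_hom_carriers = integer()))
  in_pool <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(pools))) {
    in_pool <- in_pool | (variants$chrom == pools$chrom[i] &
                            variants$pos_bp >= pools$consensus_start_bp[i] &
                            variants$pos_bp <= pools$consensus_end_bp[i])
  }
  if (any(!in_pool)) {
    inform(sprintf("excluded %d variant(s) outside every pool consensus",
                   sum(!in_pool)))
  }
  out <- variants[in_pool, , drop = FALSE]
  out$n_hom_carriers <- vapply(out$genotypes, function(g) {
    sum(g == 2L, na.rm = TRUE)
  }, integer(1))
  out <- out[out$max_credible_af <= af_max &
               consequence_in_set(out$consequence, consequence_set) &
               out$n_hom_carriers >= 1L, , drop = FALSE]
  stopifnot(all(out$max_credible_af <= af_max))
  out
}

#' Rank prioritized candidates for reporting
#'
#' Orders variants by consequence severity class (protein-truncating, then
#' splice-disrupting, then missense/in-frame), then ascending allele
#' frequency, then genomic position.
#'
#' @param variants tibble from [prioritize_variants()].
#' @return The same tibble, reordered, with a `severity_class` column.
#' @export
rank_candidates <- function(variants) {
  if (nrow(variants) == 0) {
    return(mutate(variants, severity_class = integer()))
  }
  truncating <- c("stop_gained", "stop_lost", "start_lost", "frameshift_variant")
  splice <- c("splice_donor_variant", "splice_acceptor_variant")
  cls <- ifelse(consequence_in_set(variants$consequence, truncating), 1L,
         ifelse(consequence_in_set(variants$consequence, splice), 2L, 3L))
  variants$severity_class <- cls
  arrange(variants, .data$severity_class, .data$max_credible_af,
          .data$chrom, .data$pos_bp)
}
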