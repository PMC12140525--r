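#' Construct a genotype dataset
#'
#' The in-memory substrate of the pipeline: a samples x variants genotype
#' matrix plus a sample sheet and a variant map. Genotypes are coded
#' `0` (homozygous allele 1), `1` (heterozygous), `2` (homozygous allele 2)
#' and `NA` (missing). Only autosomes 1-22 are admitted; the variant map must
#' be strictly sorted by (chromosome, position).
#'
#' @param genotypes integer matrix, samples in rows, variants in columns.
#' @param sample_sheet tibble with at least `sample_id`; recognised columns are
#'   `family_id`, `sex` ("male"/"female"/"unknown"), `phenotype`
#'   ("case"/"control"/"unknown"), `age_at_sampling`, `age_at_onset`,
#'   `ancestry_label`.
#' @param variant_map tibble with columns `chrom` (integer 1-22), `pos_bp`
#'   (1-based), `variant_id`, `allele1`, `allele2`.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, sample_sheet, variant_map) {
  sample_sheet <- as_tibble(sample_sheet)
  variant_map <- as_tibble(variant_map)
  if (!"sample_id" %in% names(sample_sheet)) {
    abort("sample_sheet must have a sample_id column")
  }
  defaults <- list(
    family_id = sample_sheet$sample_id %||% character(),
    sex = "unknown", phenotype = "unknown",
    age_at_sampling = NA_real_, age_at_onset = NA_real_,
    ancestry_label = "ALL"
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(sample_sheet)) sample_sheet[[nm]] <- defaults[[nm]]
  }
  if (anyDuplicated(sample_sheet$sample_id)) {
    abort("duplicate sample_id in sample_sheet")
  }
  req <- c("chrom", "pos_bp", "variant_id", "allele1", "allele2")
  missing_cols <- setdiff(req, names(variant_map))
  if (length(missing_cols)) {
    abort(paste("variant_map missing columns:", paste(missing_cols, collapse = ", ")))
  }
  variant_map$chrom <- as.integer(variant_map$chrom)
  variant_map$pos_bp <- as.integer(variant_map$pos_bp)
  if (any(is.na(variant_map$chrom)) ||
      any(variant_map$chrom < 1L) || any(variant_map$chrom > 22L)) {
    abort("variant_map chrom must be autosomes 1-22")
  }
  if (any(variant_map$pos_bp < 1L)) abort("pos_bp must be >= 1")
  o <- order(variant_map$chrom, variant_map$pos_bp)
  if (is.unsorted(o, strictly = TRUE) || any(o != seq_along(o))) {
    abort("variant_map must be sorted by (chrom, pos_bp)")
  }
  key <- paste(variant_map$chrom, variant_map$pos_bp, variant_map$variant_id)
  if (anyDuplicated(key)) abort("duplicate (chrom, pos, id) in variant_map")
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(sample_sheet) ||
      ncol(genotypes) != nrow(variant_map)) {
    abort(sprintf(
      "genotype matrix is %d x %d but sheet/map imply %d x %d",
      nrow(genotypes), ncol(genotypes), nrow(sample_sheet), nrow(variant_map)
    ))
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("genotype codes must be 0, 1, 2 or NA")
  }
  dimnames(genotypes) <- list(sample_sheet$sample_id, variant_map$variant_id)
  structure(
    list(genotypes = genotypes, sample_sheet = sample_sheet,
         variant_map = variant_map),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "<genotype_dataset> %d samples x %d variants on %d autosome(s)\n",
    nrow(x$genotypes), ncol(x$genotypes), length(unique(x$variant_map$chrom))
  ))
  ph <- table(factor(x$sample_sheet$phenotype, c("case", "control", "unknown")))
  cat(sprintf("  cases: %d  controls: %d  unknown: %d\n",
              ph[["case"]], ph[["control"]], ph[["unknown"]]))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

# Subset a dataset by sample and/or variant index, keeping all parts aligned.
subset_dataset <- function(dataset, samples = NULL, variants = NULL) {
  g <- dataset$genotypes
  sheet <- dataset$sample_sheet
  map <- dataset$variant_map
  if (!is.null(samples)) {
    g <- g[samples, , drop = FALSE]
    sheet <- sheet[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    g <- g[, variants, drop = FALSE]
    map <- map[variants, , drop = FALSE]
  }
  genotype_dataset(g, sheet, map)
}

# Allele-2 frequency per variant from non-missing genotypes (NaN if all missing).
allele2_freq <- function(genotypes) {
  colSums(genotypes, na.rm = TRUE) / (2 * colSums(!is.na(genotypes)))
}
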