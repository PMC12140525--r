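#' Read a gene-region table
#'
#' Reads a TSV of named genomic intervals (known recessive Parkinson's disease
#' genes, GWAS risk loci, pallido-pyramidal and atypical parkinsonism genes)
#' with columns `name`, `chrom`, `start_bp`, `end_bp`, `category`. Coordinates
#' are 1-based inclusive.
#'
#' @param path TSV path with a header row.
#' @return A tibble of validated regions.
#' @export
read_gene_regions <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("name", "chrom", "start_bp", "end_bp", "category")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste("gene-region file missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df[req])
  df$chrom <- as.integer(df$chrom)
  df$start_bp <- as.integer(df$start_bp)
  df$end_bp <- as.integer(df$end_bp)
  if (any(df$start_bp > df$end_bp)) {
    abort("gene region with start_bp > end_bp")
  }
  df
}

#' Export ROH segments as a BED file
#'
#' Converts the package's 1-based inclusive segment coordinates to BED's
#' 0-based half-open convention (`start - 1`, `end`). This export is the only
#' place 0-based coordinates appear.
#'
#' @param segments segment tibble with `sample_id`, `chrom`, `start_bp`,
#'   `end_bp` (1-based inclusive).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  out <- data.frame(
    chrom = segments$chrom,
    start = segments$start_bp - 1L,
    end = segments$end_bp,
    name = segments$sample_id
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ROH segments from a BED file
#'
#' Inverse of [write_segments_bed()]: restores 1-based inclusive coordinates.
#'
#' @param path BED path (chrom, start, end, name).
#' @return A tibble with `sample_id`, `chrom`, `start_bp`, `end_bp`.
#' @export
read_segments_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  tibble(
    sample_id = as.character(df[[4]]),
    chrom = as.integer(df[[1]]),
    start_bp = as.integer(df[[2]]) + 1L,
    end_bp = as.integer(df[[3]])
  )
}
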