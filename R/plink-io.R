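# PLINK 1 binary (BED v1.00, SNP-major) codec.
#
# Each BED byte packs four genotypes, sample-major within a variant, lowest
# bit-pair first. Two-bit codes: 00 = homozygous allele1, 01 = missing,
# 10 = heterozygous, 11 = homozygous allele2. Internal codes are the allele-2
# dosage 0/1/2 with NA for missing.

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: byte value -> four internal genotype codes.
bed_decode_table <- local({
  tab <- matrix(NA_integer_, 256L, 4L)
  code_of <- c(`0` = 0L, `1` = NA_integer_, `2` = 1L, `3` = 2L)
  for (b in 0:255) {
    for (j in 0:3) {
      tab[b + 1L, j + 1L] <- code_of[[as.character(bitwAnd(bitwShiftR(b, 2L * j), 3L))]]
    }
  }
  tab
})

# internal code (NA, 0, 1, 2) -> 2-bit value
bed_bits_of_code <- function(g) {
  out <- integer(length(g))
  out[is.na(g)] <- 1L
  out[!is.na(g) & g == 1L] <- 2L
  out[!is.na(g) & g == 2L] <- 3L
  out
}

#' Read a PLINK binary fileset
#'
#' Reads a BED/BIM/FAM triple (PLINK 1 binary, SNP-major) into a
#' [genotype_dataset()]. Non-autosomal variants (anything outside chromosomes
#' 1-22) are dropped with a message. FAM phenotype codes follow the PLINK
#' dialect: 1 = control, 2 = case, 0/-9 = unknown; sex 1 = male, 2 = female,
#' 0 = unknown.
#'
#' @param prefix path prefix, or explicit `bed`/`bim`/`fam` paths.
#' @param bed,bim,fam optional explicit file paths overriding `prefix`.
#' @return A [genotype_dataset()].
#' @export
read_plink <- function(prefix, bed = NULL, bim = NULL, fam = NULL) {
  bed <- bed %||% paste0(prefix, ".bed")
  bim <- bim %||% paste0(prefix, ".bim")
  fam <- fam %||% paste0(prefix, ".fam")
  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                       colClasses = c("character", "character", "character",
                                      "character", "integer", "integer"))
  names(fam_df) <- c("family_id", "sample_id", "pat", "mat", "sex_code", "pheno_code")
  bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                       colClasses = c("character", "character", "numeric",
                                      "integer", "character", "character"))
  names(bim_df) <- c("chrom", "variant_id", "cm", "pos_bp", "allele1", "allele2")
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:3], BED_MAGIC)) {
    if (length(raw) >= 3L && identical(raw[1:2], BED_MAGIC[1:2])) {
      abort("BED file is not SNP-major (v1.00); individual-major files are not supported")
    }
    abort("not a PLINK BED file: bad magic bytes")
  }
  bytes_per_variant <- ceiling(n / 4)
  if (length(raw) != 3L + bytes_per_variant * m) {
    abort(sprintf(
      "BED size (%d bytes) inconsistent with %d samples x %d variants",
      length(raw), n, m
    ))
  }
  body <- as.integer(raw[-(1:3)])
  # decode: each byte expands to 4 codes; rows of `geno` are samples
  geno <- matrix(NA_integer_, n, m)
  if (m > 0 && n > 0) {
    codes <- bed_decode_table[body + 1L, , drop = FALSE] # (bytes) x 4
    codes <- matrix(t(codes), nrow = 4L * bytes_per_variant)  # per-variant columns
    geno <- codes[seq_len(n), , drop = FALSE]
  }
  chrom_int <- suppressWarnings(as.integer(bim_df$chrom))
  keep <- !is.na(chrom_int) & chrom_int >= 1L & chrom_int <= 22L
  if (any(!keep)) {
    inform(sprintf("dropped %d non-autosomal variant(s)", sum(!keep)))
  }
  sheet <- tibble(
    sample_id = fam_df$sample_id,
    family_id = fam_df$family_id,
    sex = c("unknown", "male", "female")[
      ifelse(fam_df$sex_code %in% c(1L, 2L), fam_df$sex_code + 1L, 1L)],
    phenotype = ifelse(fam_df$pheno_code == 2L, "case",
                ifelse(fam_df$pheno_code == 1L, "control", "unknown"))
  )
  map <- tibble(
    chrom = chrom_int[keep],
    pos_bp = bim_df$pos_bp[keep],
    variant_id = bim_df$variant_id[keep],
    allele1 = bim_df$allele1[keep],
    allele2 = bim_df$allele2[keep]
  )
  genotype_dataset(geno[, keep, drop = FALSE], sheet, map)
}

#' Write a PLINK binary fileset
#'
#' Writes a [genotype_dataset()] as a BED/BIM/FAM triple readable by
#' [read_plink()] (and by PLINK itself). The BIM centimorgan column is 0.
#'
#' @param dataset a [genotype_dataset()].
#' @param prefix output path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(dataset, prefix) {
  g <- dataset$genotypes
  n <- nrow(g)
  m <- ncol(g)
  bytes_per_variant <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  if (m > 0 && n > 0) {
    bits <- rbind(matrix(bed_bits_of_code(g), n, m),
                  matrix(0L, 4L * bytes_per_variant - n, m))
    quads <- matrix(as.vector(bits), nrow = 4L)   # one column per packed byte
    bytes <- colSums(quads * c(1L, 4L, 16L, 64L))
    writeBin(as.raw(bytes), con)
  }
  sheet <- dataset$sample_sheet
  fam <- data.frame(
    sheet$family_id, sheet$sample_id, 0L, 0L,
    ifelse(sheet$sex == "male", 1L, ifelse(sheet$sex == "female", 2L, 0L)),
    ifelse(sheet$phenotype == "case", 2L,
           ifelse(sheet$phenotype == "control", 1L, 0L))
  )
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  map <- dataset$variant_map
  bim <- data.frame(map$chrom, map$variant_id, rep(0, nrow(map)), map$pos_bp,
                    map$allele1, map$allele2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
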