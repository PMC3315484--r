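#' Read a PLINK bed/bim/fam fileset
#'
#' Reads variant-major binary genotypes. The bed file must start with the
#' magic bytes `0x6C 0x1B` and the variant-major mode byte `0x01`
#' (sample-major files are rejected). Each SNP record packs four subjects
#' per byte, low bits first, with the 2-bit codes `00` = two copies of the
#' bim allele 1, `10` = heterozygote, `11` = zero copies, and `01` =
#' missing. Dosages count the bim allele-1 (by convention the minor)
#' allele; subject order follows the fam file.
#'
#' @param prefix Path prefix (reads `<prefix>.bed/.bim/.fam`), or the bed
#'   path itself.
#' @return A `genotype_matrix`.
#' @export
read_plink <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")

  fam_df <- utils::read.table(fam,
    col.names = c("FID", "IID", "father", "mother", "sex", "pheno"),
    colClasses = c("character", "character", "character", "character", NA, NA)
  )
  bim_df <- utils::read.table(bim,
    col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"),
    colClasses = c(NA, "character", NA, NA, "character", "character")
  )
  m <- nrow(fam_df)
  n <- nrow(bim_df)

  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B)) {
    abort("Not a PLINK bed file (magic bytes 0x6C 0x1B missing).")
  }
  if (raw[3] == as.raw(0x00)) {
    abort("Sample-major bed files are not supported; use variant-major (mode 0x01).")
  }
  if (raw[3] != as.raw(0x01)) {
    abort("Unknown bed mode byte; expected 0x01 (variant-major).")
  }
  bytes_per_snp <- ceiling(m / 4)
  expected <- 3 + bytes_per_snp * n
  if (length(raw) != expected) {
    abort(sprintf(
      "bed record length mismatch: %d bytes found, %d expected for %d subjects x %d SNPs.",
      length(raw), expected, m, n
    ))
  }

  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit codes, low bits first
  codes <- matrix(0L, 4 * bytes_per_snp, n)
  chunk <- matrix(body, bytes_per_snp, n)
  codes[seq(1, by = 4, length.out = bytes_per_snp), ] <- chunk %% 4L
  codes[seq(2, by = 4, length.out = bytes_per_snp), ] <- (chunk %/% 4L) %% 4L
  codes[seq(3, by = 4, length.out = bytes_per_snp), ] <- (chunk %/% 16L) %% 4L
  codes[seq(4, by = 4, length.out = bytes_per_snp), ] <- (chunk %/% 64L) %% 4L
  codes <- codes[seq_len(m), , drop = FALSE]

  # 00 -> 2 copies of a1, 10 -> 1, 11 -> 0, 01 -> missing
  dosage <- matrix(NA_integer_, m, n)
  dosage[codes == 0L] <- 2L
  dosage[codes == 2L] <- 1L
  dosage[codes == 3L] <- 0L
  dimnames(dosage) <- list(fam_df$IID, bim_df$snp_id)

  new_genotype_matrix(dosage = dosage, map = as_tibble(bim_df))
}

#' Write a genotype matrix as PLINK bed/bim/fam
#'
#' Writes variant-major binary genotypes (magic bytes `0x6C 0x1B 0x01`)
#' with the 2-bit coding described in [read_plink()].
#'
#' @param geno A `genotype_matrix`.
#' @param prefix Output path prefix.
#' @return The bed path, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  x <- geno$dosage
  m <- nrow(x)
  n <- ncol(x)

  codes <- matrix(1L, m, n) # 01 = missing
  codes[!is.na(x) & x == 2L] <- 0L
  codes[!is.na(x) & x == 1L] <- 2L
  codes[!is.na(x) & x == 0L] <- 3L

  bytes_per_snp <- ceiling(m / 4)
  pad <- 4 * bytes_per_snp - m
  if (pad > 0) codes <- rbind(codes, matrix(0L, pad, n))
  i1 <- seq(1, by = 4, length.out = bytes_per_snp)
  packed <- codes[i1, , drop = FALSE] +
    4L * codes[i1 + 1, , drop = FALSE] +
    16L * codes[i1 + 2, , drop = FALSE] +
    64L * codes[i1 + 3, , drop = FALSE]

  bed <- paste0(prefix, ".bed")
  con <- file(bed, "wb")
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(as.raw(packed), con)
  close(con)

  map <- geno$map
  utils::write.table(
    data.frame(map$chrom, map$snp_id, map$cm, map$pos, map$a1, map$a2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  utils::write.table(
    data.frame(geno$subject_ids, geno$subject_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(bed)
}

#' Write a tab-delimited phenotype/covariate table
#'
#' Standard layout: `FID`, `IID`, then named columns; missing values as
#' `NA`.
#'
#' @param pheno Data frame with `FID` and `IID` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(pheno, path) {
  if (!all(c("FID", "IID") %in% names(pheno))) {
    abort("Phenotype table needs FID and IID columns.")
  }
  utils::write.table(pheno, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Read a tab-delimited phenotype/covariate table
#'
#' @param path File with `FID`, `IID`, and named columns.
#' @return A tibble.
#' @export
read_phenotype_table <- function(path) {
  as_tibble(utils::read.table(path,
    header = TRUE, sep = "\t",
    colClasses = c(FID = "character", IID = "character")
  ))
}
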