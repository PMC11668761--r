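# PLINK 1 binary codec.  The .bed payload is SNP-major: per SNP,
# ceiling(n/4) bytes, 2 bits per sample filled from the least significant
# bit pair upward.  Bit-pair codes: 00 = homozygous A1 (A2-dosage 0),
# 01 = missing, 10 = heterozygous (1), 11 = homozygous A2 (2).

# 256 x 4 lookup: dosage of the s-th sample encoded in a byte value
.bedDecodeTable <- local({
  tab <- matrix(NA_integer_, 256L, 4L)
  code <- c(0L, NA_integer_, 1L, 2L)       # bit pairs 00, 01, 10, 11
  for (b in 0:255)
    for (s in 0:3)
      tab[b + 1L, s + 1L] <- code[bitwAnd(bitwShiftR(b, 2L * s), 3L) + 1L]
  tab
})

#' Read a PLINK 1 binary fileset
#'
#' Reads `<prefix>.bed` / `.bim` / `.fam` into a [GenotypeMatrix-class].
#' The .bed file must carry the magic bytes `6C 1B` and the SNP-major mode
#' byte `01`; dosages count copies of the A2 allele (the second .bim
#' allele), with missing calls as `NA`.
#'
#' @param prefix path without extension.
#' @return A [GenotypeMatrix-class].
#' @export
readPlink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  famTab <- .readFam(fam)
  bimTab <- .readBim(bim)
  n <- nrow(famTab); m <- nrow(bimTab)
  raw <- readBin(bed, what = "raw", n = file.info(bed)$size)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bed)
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major .bed files are supported (mode byte ",
         as.integer(raw[3L]), "): ", bed)
  bytesPerSnp <- ceiling(n / 4)
  if (length(raw) - 3L != bytesPerSnp * m)
    stop(sprintf(".bed payload size %d does not match %d samples x %d SNPs",
                 length(raw) - 3L, n, m))
  dosage <- matrix(NA_integer_, n, m)
  if (m > 0L && n > 0L) {
    payload <- as.integer(raw[-(1:3)]) + 1L
    dim(payload) <- c(bytesPerSnp, m)
    sampleByte <- ((seq_len(n) - 1L) %/% 4L) + 1L
    sampleSlot <- ((seq_len(n) - 1L) %% 4L) + 1L
    for (j in seq_len(m))
      dosage[, j] <- .bedDecodeTable[cbind(payload[sampleByte, j], sampleSlot)]
  }
  new("GenotypeMatrix", dosage = dosage, snps = bimTab, samples = famTab)
}

.readBim <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), id = character(), cm = numeric(),
                      pos = integer(), a1 = character(), a2 = character(),
                      stringsAsFactors = FALSE))
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  names(tab) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  tab
}

.readFam <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(fid = character(), iid = character(),
                      pat = character(), mat = character(), sex = integer(),
                      pheno = numeric(), stringsAsFactors = FALSE))
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "character", "integer", "numeric"))
  names(tab) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  tab
}

#' Write a PLINK 1 binary fileset
#'
#' Inverse of [readPlink()]: SNP-major .bed with magic `6C 1B 01`, 6-column
#' .bim and .fam.  Padding bits beyond the last sample in a byte are 0.
#'
#' @param g a [GenotypeMatrix-class].
#' @param prefix output path without extension.
#' @export
writePlink <- function(g, prefix) {
  stopifnot(is(g, "GenotypeMatrix"))
  n <- nrow(g@dosage); m <- ncol(g@dosage)
  enc <- c(0L, 2L, 3L)                      # dosage 0,1,2 -> bit pair
  bytesPerSnp <- ceiling(n / 4)
  out <- raw(3L + bytesPerSnp * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  if (m > 0L && n > 0L) {
    codes <- matrix(1L, n, m)               # 01 = missing
    obs <- !is.na(g@dosage)
    codes[obs] <- enc[g@dosage[obs] + 1L]
    pad <- bytesPerSnp * 4L - n
    if (pad > 0L)
      codes <- rbind(codes, matrix(0L, pad, m))
    shift <- 4L^((seq_len(nrow(codes)) - 1L) %% 4L)
    byteRow <- ((seq_len(nrow(codes)) - 1L) %/% 4L) + 1L
    vals <- rowsum(codes * shift, byteRow)  # bytesPerSnp x m
    out[-(1:3)] <- as.raw(as.vector(vals))
  }
  writeBin(out, paste0(prefix, ".bed"))
  write.table(g@snps, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(g@samples, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}
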