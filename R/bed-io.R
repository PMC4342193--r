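#' Read a PLINK 1 binary fileset
#'
#' Reads the variant-major packed binary genotype format: a `.bed` payload
#' (magic bytes `0x6C 0x1B`, mode byte `0x01`) plus its `.bim` variant table
#' and `.fam` sample table. Each variant occupies `ceiling(n_samples/4)`
#' bytes; pad bits beyond the last sample are ignored.
#'
#' @param bed,bim,fam paths to the three files, or give `prefix` instead.
#' @param prefix common path prefix; expands to `prefix.bed` etc.
#' @return A [new_dataset()] object.
#' @export
read_bed <- function(bed = NULL, bim = NULL, fam = NULL, prefix = NULL) {
  if (!is.null(prefix)) {
    bed <- paste0(prefix, ".bed")
    bim <- paste0(prefix, ".bim")
    fam <- paste0(prefix, ".fam")
  }
  if (is.null(bed) || is.null(bim) || is.null(fam))
    stop("either prefix or all of bed/bim/fam must be given")
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a .bed file: bad magic bytes in ", bed)
  if (raw[3] == as.raw(0x00))
    stop("sample-major unsupported: mode byte 0x00 in ", bed)
  if (raw[3] != as.raw(0x01))
    stop("unknown .bed mode byte in ", bed)
  samples <- read_fam(fam)
  variants <- read_bim(bim)
  n <- nrow(samples)
  m <- nrow(variants)
  bpv <- bytes_per_variant(n)
  payload <- raw[-(1:3)]
  if (length(payload) != bpv * m)
    stop(sprintf(
      ".bed payload truncated or oversized: %d bytes found, %d expected for %d samples x %d variants",
      length(payload), bpv * m, n, m))
  g <- structure(list(n_samples = n, n_variants = m, data = payload),
                 class = "packed_genotypes")
  ds <- structure(list(samples = samples, variants = variants, genotypes = g),
                  class = "popgen_dataset")
  validate_dataset(ds)
  ds
}

read_bim <- function(path) {
  v <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric",
                                        "integer", "character", "character"))
  names(v) <- c("chrom", "vid", "cm", "bp", "a1", "a2")
  v
}

read_fam <- function(path) {
  s <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character",
                                        "character", "integer", "numeric"))
  names(s) <- c("fid", "iid", "pid", "mid", "sex", "phenotype")
  s
}

#' Write a PLINK 1 binary fileset
#'
#' Emits `prefix.bed` (variant-major, mode byte 0x01), `prefix.bim` and
#' `prefix.fam`, readable by [read_bed()] and by other tools that consume
#' this format. An empty dataset produces a `.bed` of exactly the three
#' header bytes.
#'
#' @param dataset a `popgen_dataset`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_bed <- function(dataset, prefix) {
  validate_dataset(dataset)
  g <- dataset$genotypes
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(g$data, con)
  v <- dataset$variants
  utils::write.table(
    data.frame(v$chrom, v$vid, v$cm, v$bp, v$a1, v$a2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  s <- dataset$samples
  utils::write.table(
    data.frame(s$fid, s$iid, s$pid, s$mid, s$sex, s$phenotype),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
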