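#' Packed genotype matrix
#'
#' Variant-major, 2-bit-per-call genotype store. Each call occupies two bits
#' (`00` = homozygous a1, `01` = missing, `10` = heterozygous,
#' `11` = homozygous a2), four calls per byte with the first sample in the
#' two lowest-order bits, and every variant row padded to a whole number of
#' bytes. Pad calls carry the fixed code 00 and never influence any kernel.
#'
#' Unpacked genotypes are integer dosages of the a2 allele
#' (0 = hom a1, 1 = het, 2 = hom a2, `NA` = missing).
#'
#' @param geno integer matrix, samples in rows, variants in columns,
#'   values 0/1/2/`NA`.
#' @return An object of class `packed_genotypes` with fields `n_samples`,
#'   `n_variants` and `data` (raw vector).
#' @export
pack_genotypes <- function(geno) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  structure(
    list(n_samples = nrow(geno), n_variants = ncol(geno),
         data = .pack_genotypes_cpp(geno)),
    class = "packed_genotypes")
}

#' @rdname pack_genotypes
#' @param x a `packed_genotypes` object or a `popgen_dataset`.
#' @export
unpack_genotypes <- function(x) {
  g <- genotypes(x)
  .unpack_genotypes_cpp(g$data, g$n_samples, g$n_variants)
}

genotypes <- function(x) {
  if (inherits(x, "popgen_dataset")) x$genotypes
  else if (inherits(x, "packed_genotypes")) x
  else stop("expected a popgen_dataset or packed_genotypes object")
}

bytes_per_variant <- function(n_samples) (n_samples + 3L) %/% 4L

#' @export
print.packed_genotypes <- function(x, ...) {
  cat(sprintf("<packed_genotypes: %d samples x %d variants, %d bytes>\n",
              x$n_samples, x$n_variants, length(x$data)))
  invisible(x)
}

#' Assemble a dataset
#'
#' A dataset bundles the sample table (.fam fields), the variant table
#' (.bim fields) and the packed genotype matrix.
#'
#' @param genotypes a `packed_genotypes` object or an unpacked genotype
#'   matrix (samples x variants).
#' @param samples data frame with columns `fid`, `iid`, `pid`, `mid`, `sex`
#'   (1 = male, 2 = female, 0 = unknown) and `phenotype` (-9 = missing);
#'   defaults are generated when omitted.
#' @param variants data frame with columns `chrom`, `vid`, `cm`, `bp`,
#'   `a1`, `a2`; defaults are generated when omitted.
#' @return An object of class `popgen_dataset`.
#' @export
new_dataset <- function(genotypes, samples = NULL, variants = NULL) {
  if (!inherits(genotypes, "packed_genotypes"))
    genotypes <- pack_genotypes(genotypes)
  n <- genotypes$n_samples
  m <- genotypes$n_variants
  if (is.null(samples))
    samples <- data.frame(
      fid = sprintf("F%d", seq_len(n)), iid = sprintf("I%d", seq_len(n)),
      pid = rep("0", n), mid = rep("0", n), sex = rep(0L, n),
      phenotype = rep(-9, n), stringsAsFactors = FALSE)
  if (is.null(variants))
    variants <- data.frame(
      chrom = rep("1", m), vid = sprintf("var%d", seq_len(m)),
      cm = rep(0, m), bp = seq_len(m) * 1000L, a1 = rep("A", m),
      a2 = rep("B", m), stringsAsFactors = FALSE)
  ds <- structure(list(samples = samples, variants = variants,
                       genotypes = genotypes),
                  class = "popgen_dataset")
  validate_dataset(ds)
  ds
}

validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "popgen_dataset"))
  n <- ds$genotypes$n_samples
  m <- ds$genotypes$n_variants
  if (nrow(ds$samples) != n)
    stop("sample table has ", nrow(ds$samples), " rows but genotypes have ",
         n, " samples")
  if (nrow(ds$variants) != m)
    stop("variant table has ", nrow(ds$variants), " rows but genotypes have ",
         m, " variants")
  need_s <- c("fid", "iid", "pid", "mid", "sex", "phenotype")
  need_v <- c("chrom", "vid", "cm", "bp", "a1", "a2")
  if (!all(need_s %in% names(ds$samples))) stop("sample table lacks columns")
  if (!all(need_v %in% names(ds$variants))) stop("variant table lacks columns")
  key <- paste(ds$samples$fid, ds$samples$iid)
  if (anyDuplicated(key)) stop("duplicated (fid, iid) pairs")
  if (any(ds$variants$bp < 0)) stop("negative base-pair position")
  invisible(ds)
}

#' @export
print.popgen_dataset <- function(x, ...) {
  cat(sprintf("<popgen_dataset: %d samples, %d variants>\n",
              x$genotypes$n_samples, x$genotypes$n_variants))
  invisible(x)
}

#' @export
dim.popgen_dataset <- function(x)
  c(x$genotypes$n_samples, x$genotypes$n_variants)

# unpacked genotype column(s) for variant index j (1-based)
variant_dosages <- function(ds, j) {
  g <- genotypes(ds)
  bpv <- bytes_per_variant(g$n_samples)
  sub <- g$data[((j - 1L) * bpv + 1L):(j * bpv)]
  drop(.unpack_genotypes_cpp(sub, g$n_samples, 1L))
}

# variants sorted by (chrom, bp): chromosomes in contiguous runs, positions
# non-decreasing within each run
is_position_sorted <- function(ds) {
  v <- ds$variants
  if (nrow(v) < 2) return(TRUE)
  runs <- rle(as.character(v$chrom))$values
  if (anyDuplicated(runs)) return(FALSE)
  all(vapply(split(v$bp, factor(v$chrom, levels = unique(v$chrom))),
             function(b) !is.unsorted(b), logical(1)))
}

# keep a subset of variants (indices), preserving order
subset_variants <- function(ds, idx) {
  g <- genotypes(ds)
  bpv <- bytes_per_variant(g$n_samples)
  take <- as.vector(outer(seq_len(bpv), (idx - 1L) * bpv, `+`))
  new_g <- structure(list(n_samples = g$n_samples, n_variants = length(idx),
                          data = g$data[take]),
                     class = "packed_genotypes")
  structure(list(samples = ds$samples,
                 variants = ds$variants[idx, , drop = FALSE],
                 genotypes = new_g),
            class = "popgen_dataset")
}
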