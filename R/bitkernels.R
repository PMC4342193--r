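#' Bit population count
#'
#' Number of set bits in a bit vector, computed 64 bits at a time with a
#' pure-integer algorithm (no hardware intrinsic required).
#'
#' @param bits a raw vector, or a logical/0-1 integer vector of bits.
#' @return The count, as a double.
#' @export
popcount <- function(bits) {
  if (!is.raw(bits)) {
    b <- as.integer(bits)
    if (any(is.na(b)) || any(b < 0 | b > 1)) stop("bits must be 0/1 or raw")
    bits <- packBits(c(as.logical(b),
                       logical((8 - length(b) %% 8) %% 8)), "raw")
  }
  .popcount_raw(bits)
}

#' Sum of 2-bit fields
#'
#' `popcount2` sums 2-bit quantities instead of counting set bits: every
#' aligned 2-bit field of the input (value 0-3) contributes its integer
#' value.
#'
#' @param fields a raw vector (a sequence of 2-bit fields).
#' @return The sum, as a double.
#' @export
popcount2 <- function(fields) {
  stopifnot(is.raw(fields))
  .popcount2_raw(fields)
}

#' Identity-by-state encoding of a genotype vector
#'
#' Produces the 2-bit-per-call encoding used by the IBS kernel: per call
#' `a` = `01` for missing, `00`/`10`/`11` for dosage 0/1/2; `mask` = `00`
#' at missing calls and `11` elsewhere. The vectors are padded with missing
#' calls to a multiple of 960 calls (the kernel's block size).
#'
#' @param g integer genotype vector (0/1/2/`NA`).
#' @return list with raw vectors `a_bits` and `mask_bits`.
#' @export
ibs_encode <- function(g) .ibs_encode_cpp(as.integer(g))

#' Identity-by-state counts for a pair of genotype vectors
#'
#' Computes `diff` = sum of |a_i - b_i| and `obs` = twice the number of
#' jointly non-missing calls with the XOR/AND block kernel
#' (E := A xor B, F := C and D; diff += popcount(E and F),
#' obs += popcount(F), over 960-call blocks). The IBS similarity is
#' `(obs - diff)/obs`.
#'
#' @param a,b integer genotype vectors (0/1/2/`NA`) of equal length.
#' @return list with `diff`, `obs` and `ibs` (`NA` when no calls overlap).
#' @export
ibs_counts <- function(a, b) {
  r <- .ibs_counts_cpp(as.integer(a), as.integer(b))
  r$ibs <- if (r$obs > 0) (r$obs - r$diff) / r$obs else NA_real_
  r
}

#' Packed dot product of recoded genotypes
#'
#' Returns sum(v_i * w_i) where v, w recode dosage 0/1/2 as -1/0/+1 and
#' missing as 0, evaluated two bits per call:
#' Z := (X or Y) and 0101...; the per-call quantity
#' popcount2(((X xor Y) and (1010... - Z)) or Z) equals 1 - v_i w_i, and
#' subtracting the total from the padded call count yields the dot product.
#'
#' @param x,y integer genotype vectors (0/1/2/`NA`) of equal length.
#' @return The dot product, as a double.
#' @export
dot_product_packed <- function(x, y)
  .dot_product_packed_cpp(as.integer(x), as.integer(y))

#' Genotype tallies for one variant
#'
#' @param g integer genotype vector (0/1/2/`NA`).
#' @return named vector: `n_hom_a1`, `n_het`, `n_hom_a2`, `n_missing`.
#' @export
genotype_counts <- function(g) {
  g <- as.integer(g)
  pk <- pack_genotypes(matrix(g, ncol = 1))
  cnt <- .genotype_count_matrix_cpp(pk$data, pk$n_samples, 1L)
  stats::setNames(cnt[, 1], c("n_hom_a1", "n_het", "n_hom_a2", "n_missing"))
}
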