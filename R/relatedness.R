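#' Per-marker relationship increments for the seven genotype-pair cases
#'
#' For a variant with a1 frequency `q`, the GCTA genomic-relationship
#' increment for a sample pair with a1 dosages x, y (0, 1 or 2) is
#' `(x - 2q)(y - 2q) / (2q(1 - q))`; a pair with any missing call
#' contributes 0 and instead decrements the pair's denominator. The eight
#' entries are indexed by the packed 3-bit case code (value 1 is unused).
#'
#' @param q a1 allele frequency, strictly between 0 and 1.
#' @return named numeric vector of length 8.
#' @export
grm_case_increments <- function(q) {
  stopifnot(q > 0, q < 1)
  stats::setNames(.grm_case_increments_cpp(q),
                  c("hom1_hom1", "unused", "hom1_het", "hom1_hom2",
                    "het_het", "het_hom2", "hom2_hom2", "missing"))
}

#' 3-bit case codes for a block of up to 20 markers
#'
#' Classifies each marker's genotype pair into one of seven cases
#' (the six unordered non-missing dosage pairs, plus "any call missing")
#' and packs the 3-bit codes into a 60-bit word: marker 1 occupies bits
#' 0-2, marker 20 bits 57-59. The same packing feeds the partial-sum
#' lookup in [grm()].
#'
#' @param gx,gy integer genotype vectors (a2 dosage 0/1/2/`NA`), length
#'   at most 20.
#' @return list: `codes` (integer case code per marker), `indices` (four
#'   15-bit table indices covering markers 1-5, 6-10, 11-15, 16-20, with
#'   absent markers coded missing).
#' @export
encode_case_codes <- function(gx, gy) {
  stopifnot(length(gx) == length(gy), length(gx) >= 1, length(gx) <= 20)
  gmap <- function(g) ifelse(is.na(g), 0L, c(0L, 2L, 3L)[g + 1L])
  miss <- is.na(gx) | is.na(gy)
  codes <- gmap(gx) + gmap(gy)
  codes[miss] <- 7L
  full <- c(codes, rep(7L, 20 - length(codes)))
  idx <- vapply(0:3, function(t)
    sum(full[5 * t + 1:5] * 8L^(0:4)), numeric(1))
  list(codes = codes, indices = as.integer(idx))
}

#' Partial-sum lookup table for a 5-marker group
#'
#' Maps every 15-bit index (five packed 3-bit case codes) to the sum of the
#' five per-marker increments, so a 20-marker block costs four table
#' lookups and additions per sample pair instead of twenty.
#'
#' @param q5 a1 frequencies of the (up to five) markers in the group.
#' @return numeric vector of length 2^15.
#' @export
grm_partial_sum_table <- function(q5) {
  if (any(q5 <= 0 | q5 >= 1))
    stop("monomorphic variant (q = 0 or 1): exclude it before building tables")
  .grm_partial_sum_table_cpp(as.numeric(q5))
}

#' Genomic relationship matrix (GCTA increments, partial-sum lookup)
#'
#' Computes `A[j,k] = sum_m (x_jm - 2q_m)(x_km - 2q_m) / (2 q_m (1 - q_m))`
#' divided by the number of markers where both samples are called. Twenty
#' markers are processed per 64-bit word via 3-bit case codes and four
#' 2^15-entry partial-sum tables (rebuilt per block; about 1 MB of entries,
#' stored as 8-byte doubles). The diagonal uses the same increments with
#' x = y; no leave-one-out correction is applied to it (set
#' `diagonal_adjust` for the variant that subtracts 1 marker from diagonal
#' denominators' worth of self-correction used by some GCTA builds).
#'
#' @param dataset a `popgen_dataset`; every variant must be polymorphic
#'   (0 < q < 1) - filter monomorphic variants first.
#' @param q optional externally supplied a1 frequencies (default: sample
#'   frequencies over non-missing calls).
#' @param row_chunk optional `c(k, K)`: compute only row chunk `k` of `K`
#'   (rows `ceiling(n(k-1)/K)+1 .. ceiling(nk/K)`); chunks concatenate to
#'   the full matrix exactly, which is how very large matrices are split
#'   across runs.
#' @param lookup use the partial-sum tables (default); `FALSE` uses twenty
#'   single-case lookups per block, summed in the same order - the results
#'   are bitwise identical.
#' @return list of class `grm_result`: `values` (relationships),
#'   `denominators` (non-missing marker counts per pair), `rows` (row
#'   indices covered).
#' @export
grm <- function(dataset, q = NULL, row_chunk = NULL, lookup = TRUE) {
  g <- genotypes(dataset)
  n <- g$n_samples; m <- g$n_variants
  if (is.null(q)) q <- allele_frequencies(dataset)$a1_freq
  if (any(is.na(q)) || any(q <= 0 | q >= 1))
    stop("monomorphic or all-missing variant: exclude such variants before grm()")
  if (is.null(row_chunk)) {
    r0 <- 0L; r1 <- n
  } else {
    k <- row_chunk[1]; K <- row_chunk[2]
    stopifnot(k >= 1, k <= K)
    r0 <- as.integer(ceiling(n * (k - 1) / K))
    r1 <- as.integer(ceiling(n * k / K))
  }
  res <- .grm_cpp(g$data, n, m, as.numeric(q), r0, r1, !isTRUE(lookup))
  ids <- if (inherits(dataset, "popgen_dataset"))
    paste(dataset$samples$fid, dataset$samples$iid) else as.character(seq_len(n))
  dimnames(res$values) <- list(ids[seq(r0 + 1, length.out = r1 - r0)], ids)
  structure(list(values = res$values, denominators = res$denominators,
                 rows = seq(r0 + 1L, length.out = r1 - r0)),
            class = "grm_result")
}

#' @export
print.grm_result <- function(x, ...) {
  cat(sprintf("<grm_result: rows %d..%d, %d columns>\n",
              min(x$rows), max(x$rows), ncol(x$values)))
  invisible(x)
}

#' Sample-by-sample identity-by-state matrix
#'
#' Entry (i, j) is `(obs - diff)/obs` from the block IBS kernel: the
#' proportion of shared alleles over jointly called markers. Diagonal
#' entries are 1 wherever any call is observed; pairs with no overlapping
#' calls are `NA`.
#'
#' @inheritParams grm
#' @return list: `ibs` (similarity matrix rows), `diff`, `obs`, `rows`.
#' @export
ibs_matrix <- function(dataset, row_chunk = NULL) {
  g <- genotypes(dataset)
  n <- g$n_samples
  if (is.null(row_chunk)) {
    r0 <- 0L; r1 <- n
  } else {
    k <- row_chunk[1]; K <- row_chunk[2]
    stopifnot(k >= 1, k <= K)
    r0 <- as.integer(ceiling(n * (k - 1) / K))
    r1 <- as.integer(ceiling(n * k / K))
  }
  res <- .ibs_matrix_cpp(g$data, n, g$n_variants, r0, r1)
  ibs <- ifelse(res$obs > 0, (res$obs - res$diff) / res$obs, NA_real_)
  list(ibs = ibs, diff = res$diff, obs = res$obs,
       rows = seq(r0 + 1L, length.out = r1 - r0))
}

#' Complete-linkage hierarchical clustering
#'
#' Nearest-neighbour-chain implementation of complete linkage (merge height
#' = maximum inter-cluster pairwise distance), O(n^2) distance updates
#' instead of the naive O(n^3) scan. Ties are broken toward the smallest
#' cluster-index pair so results are deterministic. The returned object is
#' a standard `hclust`, so [stats::cophenetic()], [stats::cutree()] etc.
#' apply.
#'
#' @param distances symmetric distance matrix (for genotype data typically
#'   `1 - ibs_matrix(dataset)$ibs`) or a `dist` object.
#' @return An object of classes `popgen_hclust` and `hclust`.
#' @export
complete_linkage <- function(distances) {
  d <- as.matrix(distances)
  if (!isTRUE(all(is.finite(d)))) stop("non-finite distances")
  n <- nrow(d)
  stopifnot(n >= 2, ncol(d) == n)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  chain <- integer(0)
  nmerge <- 0L
  diag(d) <- Inf
  while (nmerge < n - 1L) {
    if (length(chain) == 0L) chain <- which(active)[1]
    top <- chain[length(chain)]
    cand <- which(active)
    cand <- cand[cand != top]
    dd <- d[top, cand]
    best <- cand[dd == min(dd)]
    prev <- if (length(chain) >= 2L) chain[length(chain) - 1L] else NA_integer_
    nn <- if (!is.na(prev) && prev %in% best) prev else min(best)
    if (!is.na(prev) && nn == prev) {
      # reciprocal nearest neighbours: merge top and prev
      i <- min(top, prev); j <- max(top, prev)
      nmerge <- nmerge + 1L
      merges[nmerge, ] <- c(i, j)
      heights[nmerge] <- d[i, j]
      upd <- pmax(d[i, ], d[j, ])
      d[i, ] <- upd; d[, i] <- upd
      d[i, i] <- Inf
      active[j] <- FALSE
      d[j, ] <- Inf; d[, j] <- Inf
      size[i] <- size[i] + size[j]
      chain <- chain[seq_len(length(chain) - 2L)]
    } else chain <- c(chain, nn)
  }
  # order merges by height (stable) and rebuild hclust-style merge codes
  ord <- order(heights)
  heights <- heights[ord]
  merges <- merges[ord, , drop = FALSE]
  slot_code <- rep(NA_integer_, n) # last merge index involving each slot
  merge_out <- matrix(0L, n - 1, 2)
  for (s in seq_len(n - 1L)) {
    i <- merges[s, 1]; j <- merges[s, 2]
    ci <- if (is.na(slot_code[i])) -i else slot_code[i]
    cj <- if (is.na(slot_code[j])) -j else slot_code[j]
    lo <- if (ci < 0 && cj < 0) c(max(ci, cj), min(ci, cj))
          else if (ci < 0) c(ci, cj) else if (cj < 0) c(cj, ci)
          else c(min(ci, cj), max(ci, cj))
    merge_out[s, ] <- lo
    slot_code[i] <- s
    slot_code[j] <- s
  }
  hc <- structure(list(merge = merge_out, height = heights,
                       order = integer(n), labels = labels,
                       method = "complete",
                       call = match.call(), dist.method = "user"),
                  class = c("popgen_hclust", "hclust"))
  hc$order <- hclust_order(merge_out, n)
  hc
}

# leaf order by recursive traversal of the merge tree
hclust_order <- function(merge, n) {
  leaves <- function(k)
    if (k < 0) -k else c(leaves(merge[k, 1]), leaves(merge[k, 2]))
  out <- leaves(n - 1L)
  stopifnot(length(out) == n)
  out
}
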