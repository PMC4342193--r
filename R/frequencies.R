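#' Per-variant allele frequencies
#'
#' Counts are tallied with bit population counts on the packed rows;
#' missing calls are excluded from the denominator.
#'
#' @param dataset a `popgen_dataset`.
#' @return data frame with one row per variant: `vid`, `a1_count`,
#'   `obs_allele_count`, `a1_freq` (= a1_count / obs_allele_count), `maf`
#'   (folded to the minor allele) and `all_missing`. Variants with no
#'   observed calls have `NA` frequencies and `all_missing = TRUE`;
#'   monomorphic variants have `maf` 0.
#' @export
allele_frequencies <- function(dataset) {
  g <- genotypes(dataset)
  cnt <- .genotype_count_matrix_cpp(g$data, g$n_samples, g$n_variants)
  a1 <- 2 * cnt[1, ] + cnt[2, ]
  obs <- 2 * (g$n_samples - cnt[4, ])
  f <- ifelse(obs > 0, a1 / obs, NA_real_)
  data.frame(
    vid = if (inherits(dataset, "popgen_dataset")) dataset$variants$vid
          else sprintf("var%d", seq_len(g$n_variants)),
    a1_count = a1, obs_allele_count = obs,
    a1_freq = f, maf = pmin(f, 1 - f),
    all_missing = obs == 0,
    stringsAsFactors = FALSE)
}
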