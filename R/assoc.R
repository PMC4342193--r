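# case/control association statistics and max(T) permutation testing

# normalise a phenotype vector to 1 = case, 0 = control, NA = missing.
# Accepts logical, 0/1, or PLINK 1/2 coding (-9 and 0 missing).
normalize_status <- function(phenotype) {
  if (is.logical(phenotype)) return(ifelse(is.na(phenotype), NA_integer_,
                                           as.integer(phenotype)))
  p <- as.numeric(phenotype)
  p[p %in% c(-9, 0) & any(p %in% c(2, -9), na.rm = TRUE)] <- NA
  vals <- sort(unique(p[!is.na(p)]))
  if (all(vals %in% c(0, 1))) return(as.integer(p))
  if (all(vals %in% c(1, 2))) return(as.integer(p) - 1L)
  stop("phenotype is not case/control coded (use 0/1, 1/2 or logical)")
}

#' Allele-count table for a variant by case status
#'
#' 2x2 allele counts (rows case/control, columns a1/a2) computed with
#' masked population counts over the packed row; missing genotypes and
#' unphenotyped samples are excluded.
#'
#' @param x integer genotype vector (0/1/2/`NA`), or a `popgen_dataset`
#'   (then all variants are tabulated).
#' @param status case mask: logical / 0-1 / PLINK 1-2 coding, `NA` or
#'   -9 = missing.
#' @return For a vector, a 2x2 matrix; for a dataset, a 4 x m matrix with
#'   rows case_a1, case_a2, ctrl_a1, ctrl_a2.
#' @export
allelic_counts <- function(x, status) {
  st <- normalize_status(status)
  if (inherits(x, "popgen_dataset") || inherits(x, "packed_genotypes")) {
    g <- genotypes(x)
    stopifnot(length(st) == g$n_samples)
    out <- .allelic_counts_cpp(g$data, g$n_samples, g$n_variants, st)
    rownames(out) <- c("case_a1", "case_a2", "ctrl_a1", "ctrl_a2")
    return(out)
  }
  pk <- pack_genotypes(matrix(as.integer(x), ncol = 1))
  cnt <- .allelic_counts_cpp(pk$data, pk$n_samples, 1L, st)
  matrix(cnt[, 1], 2, 2, byrow = TRUE,
         dimnames = list(c("case", "control"), c("a1", "a2")))
}

#' Cochran-Armitage trend statistic
#'
#' Standard trend chi-square with genotype weights (0, 1, 2) on a 2x3
#' genotype-by-status table (rows case/control, columns dosage 0/1/2). The
#' statistic is invariant to swapping case and control labels and to
#' reversing the weights. Degenerate margins (no variation in genotype or
#' status) make it undefined and return `NA`.
#'
#' @param table 2x3 matrix of counts.
#' @return The chi-square-distributed statistic (1 df), or `NA`.
#' @export
trend_statistic <- function(table) {
  stopifnot(is.matrix(table), nrow(table) == 2, ncol(table) == 3)
  r <- table[1, ]; n <- colSums(table)
  N <- sum(n); R <- sum(r)
  w <- 0:2
  varpart <- R * (N - R) * (N * sum(w^2 * n) - sum(w * n)^2)
  if (varpart <= 0 || N <= 1) return(NA_real_)
  num <- N * sum(w * r) - R * sum(w * n)
  N * num^2 / varpart
}

#' max(T) permutation association test
#'
#' For each of `R` permutations, case labels are reshuffled among the
#' phenotyped samples (case count fixed), every variant's statistic is
#' recomputed through masked population counts on precomputed bitplanes,
#' and the per-permutation extremum is recorded. Pointwise empirical
#' p-values use the (k+1)/(R+1) estimator; the family-wise-corrected value
#' compares each observed statistic against the distribution of the
#' per-permutation maxima (minimum p for the Fisher mode), so
#' `p_corrected >= p_pointwise` always. Identical inputs and seed give
#' identical reports.
#'
#' Statistics: `trend` = Cochran-Armitage trend chi-square; `allelic` =
#' 1-df allelic chi-square; `fisher` = early-termination Fisher exact p on
#' the 2x2 allele table. Per-variant statistics use that variant's
#' non-missing samples.
#'
#' @param dataset a `popgen_dataset`.
#' @param phenotype case/control vector (see [allelic_counts()]); defaults
#'   to the sample table's phenotype column.
#' @param test `"trend"`, `"allelic"` or `"fisher"`.
#' @param R number of permutations.
#' @param seed integer seed for the permutation generator.
#' @return list of class `permutation_report`: `table` (data frame with
#'   `vid`, `stat`, `emp_pointwise`, `emp_corrected`), `extrema`, `R`,
#'   `seed`, `test`.
#' @export
max_t <- function(dataset, phenotype = NULL,
                  test = c("trend", "allelic", "fisher"),
                  R = 1000L, seed = 1L) {
  test <- match.arg(test)
  g <- genotypes(dataset)
  if (is.null(phenotype)) phenotype <- dataset$samples$phenotype
  st <- normalize_status(phenotype)
  if (length(st) != g$n_samples) stop("phenotype length mismatch")
  if (all(is.na(st)) || length(unique(st[!is.na(st)])) < 2)
    stop("phenotype is constant or all missing")
  tcode <- match(test, c("trend", "allelic", "fisher")) - 1L
  res <- .max_t_cpp(g$data, g$n_samples, g$n_variants, st, tcode,
                    as.integer(R), as.numeric(seed))
  tab <- data.frame(
    vid = if (inherits(dataset, "popgen_dataset")) dataset$variants$vid
          else sprintf("var%d", seq_len(g$n_variants)),
    stat = res$obs,
    emp_pointwise = (res$count_pointwise + 1) / (R + 1),
    emp_corrected = (res$count_max + 1) / (R + 1),
    stringsAsFactors = FALSE)
  structure(list(table = tab, extrema = res$extrema, R = R, seed = seed,
                 test = test, n_cases = res$n_cases,
                 n_phenotyped = res$n_phenotyped),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("max(T) permutation report: %s test, %d permutations, seed %s\n",
              x$test, x$R, format(x$seed)))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("...\n")
  invisible(x)
}
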