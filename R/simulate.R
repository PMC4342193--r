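#' Specification for the synthetic genotype generator
#'
#' Collects every latent parameter of [simulate_dataset()]: sample and
#' variant counts, the MAF distribution (uniform on `[maf_min, 0.5]`),
#' uniform missingness, Hardy-Weinberg or inbreeding genotype proportions,
#' LD block structure, and a case/control phenotype with optional planted
#' allelic odds ratios. A fixed spec (including its seed) always produces
#' byte-identical output.
#'
#' @param n_samples,n_variants dimensions.
#' @param maf_min lower bound of the uniform MAF distribution.
#' @param missing_rate per-call missingness probability.
#' @param hwe_mode `"equilibrium"` or `"inbreeding"` (heterozygote
#'   frequency 2pq(1-F)).
#' @param inbreeding_f inbreeding coefficient F for `"inbreeding"` mode.
#' @param ld_blocks optional data frame with columns `size` (variants) and
#'   `r2` (within-block target r^2 between adjacent variants); blocks are
#'   laid out from the first variant onward, remaining variants are
#'   independent.
#' @param case_fraction expected proportion of cases (`NA` for no
#'   phenotype).
#' @param effects optional data frame with columns `variant` (index) and
#'   `or` (allelic odds ratio on the a1 allele).
#' @param seed integer seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_samples, n_variants, maf_min = 0.05,
                     missing_rate = 0, hwe_mode = c("equilibrium", "inbreeding"),
                     inbreeding_f = 0, ld_blocks = NULL, case_fraction = 0.5,
                     effects = NULL, seed = 1L) {
  hwe_mode <- match.arg(hwe_mode)
  stopifnot(n_samples >= 1, n_variants >= 1,
            maf_min > 0, maf_min < 0.5,
            missing_rate >= 0, missing_rate < 1,
            inbreeding_f >= 0, inbreeding_f <= 1)
  if (!is.null(ld_blocks)) {
    stopifnot(all(c("size", "r2") %in% names(ld_blocks)),
              sum(ld_blocks$size) <= n_variants, all(ld_blocks$size >= 2))
    if (any(ld_blocks$r2 <= 0 | ld_blocks$r2 > 1))
      stop("infeasible r2 target (must be in (0, 1])")
  }
  if (!is.null(effects))
    stopifnot(all(c("variant", "or") %in% names(effects)),
              all(effects$variant >= 1 & effects$variant <= n_variants),
              all(effects$or > 0))
  structure(list(n_samples = n_samples, n_variants = n_variants,
                 maf_min = maf_min, missing_rate = missing_rate,
                 hwe_mode = hwe_mode, inbreeding_f = inbreeding_f,
                 ld_blocks = ld_blocks, case_fraction = case_fraction,
                 effects = effects, seed = as.integer(seed)),
            class = "sim_spec")
}

# per-site allele flip rate giving the target adjacent-pair r^2 within a
# block with latent haplotype allele frequency p
block_flip_rate <- function(p, r2_target) {
  rho <- sqrt(r2_target) # haplotype-level correlation target
  f <- function(eps) {
    q <- p * (1 - 2 * eps) + eps
    p * (1 - p) * (1 - 2 * eps)^2 / (q * (1 - q)) - rho
  }
  if (f(0) < -1e-12) stop("infeasible r2 target for this block frequency")
  if (r2_target >= 1) return(0)
  stats::uniroot(f, c(0, 0.5 - 1e-9), tol = 1e-12)$root
}

#' Simulate a genotype dataset with known truth
#'
#' Draws genotypes variant by variant from Hardy-Weinberg proportions at a
#' random MAF (heterozygote frequency shrunk by 1-F in inbreeding mode).
#' LD blocks are generated by giving each sample two latent haplotype
#' alleles per block and copying them into every block variant with a
#' per-site flip noise calibrated to the requested adjacent-pair r^2;
#' block variants sit 500 bp apart, independent variants 10 kb apart.
#' Case/control phenotypes follow a logistic model on planted allelic
#' log odds ratios, with the intercept solved so the expected case
#' fraction matches the spec. Missingness is applied uniformly at the
#' end. All draws come from R's generator seeded once from the spec, in
#' this documented order: MAFs, block haplotypes and flips, independent
#' genotypes, phenotype, missingness.
#'
#' @param spec a [sim_spec()].
#' @return list: `dataset` (a `popgen_dataset`) and `truth` (latent MAFs,
#'   block layout, flip rates, phenotype model).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; m <- spec$n_variants
  maf <- stats::runif(m, spec$maf_min, 0.5)
  geno <- matrix(NA_integer_, n, m) # a1 copies for now
  block_id <- integer(m)
  flip <- rep(NA_real_, m)
  j <- 1L
  if (!is.null(spec$ld_blocks)) {
    for (b in seq_len(nrow(spec$ld_blocks))) {
      size <- spec$ld_blocks$size[b]
      p <- maf[j] # block latent frequency: reuse the first variant's draw
      eps <- block_flip_rate(p, spec$ld_blocks$r2[b])
      h1 <- stats::rbinom(n, 1, p)
      h2 <- stats::rbinom(n, 1, p)
      for (s in seq_len(size)) {
        f1 <- stats::rbinom(n, 1, eps)
        f2 <- stats::rbinom(n, 1, eps)
        geno[, j] <- as.integer(xor(h1, f1)) + as.integer(xor(h2, f2))
        maf[j] <- p
        block_id[j] <- b
        flip[j] <- eps
        j <- j + 1L
      }
    }
  }
  F <- if (spec$hwe_mode == "inbreeding") spec$inbreeding_f else 0
  while (j <= m) {
    p <- maf[j]
    probs <- c((1 - p)^2 + F * p * (1 - p),
               2 * p * (1 - p) * (1 - F),
               p^2 + F * p * (1 - p))
    geno[, j] <- sample(0:2, n, replace = TRUE, prob = probs)
    j <- j + 1L
  }
  # phenotype: logistic on planted allelic log odds ratios
  phenotype <- rep(-9, n)
  beta0 <- NA_real_
  if (!is.na(spec$case_fraction)) {
    lp <- rep(0, n)
    if (!is.null(spec$effects))
      for (e in seq_len(nrow(spec$effects)))
        lp <- lp + log(spec$effects$or[e]) * geno[, spec$effects$variant[e]]
    fb <- function(b0) mean(stats::plogis(b0 + lp)) - spec$case_fraction
    beta0 <- stats::uniroot(fb, c(-40, 40), tol = 1e-10)$root
    status <- stats::rbinom(n, 1, stats::plogis(beta0 + lp))
    phenotype <- status + 1 # PLINK coding: 1 control, 2 case
  }
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < spec$missing_rate, n, m)
    geno[mask] <- NA_integer_
  }
  bp <- integer(m)
  pos <- 1L
  for (k in seq_len(m)) {
    bp[k] <- pos
    gap <- if (k < m && block_id[k] > 0 && block_id[k] == block_id[k + 1])
      500L else 10000L
    pos <- pos + gap
  }
  variants <- data.frame(
    chrom = "1", vid = sprintf("var%d", seq_len(m)), cm = 0, bp = bp,
    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  samples <- data.frame(
    fid = sprintf("F%d", seq_len(n)), iid = sprintf("I%d", seq_len(n)),
    pid = "0", mid = "0", sex = 0L, phenotype = phenotype,
    stringsAsFactors = FALSE)
  # stored dosage counts a2: dosage = 2 - a1 copies
  ds <- new_dataset(pack_genotypes(2L - geno), samples, variants)
  list(dataset = ds,
       truth = list(maf = maf, block_id = block_id, flip_rate = flip,
                    beta0 = beta0, effects = spec$effects,
                    inbreeding_f = F, spec = spec))
}
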