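#' Import genotypes from a VCF file (lossy)
#'
#' Converts the GT field of a text VCF (plain or gzip) to packed biallelic
#' hard calls. The conversion is deliberately lossy, mirroring the rules of
#' the packed 2-bit data model:
#'
#' * Phase separators are ignored: `0|1` and `0/1` give the same call.
#' * Multi-allelic sites: with `biallelic_only = TRUE` the variant is
#'   skipped; otherwise only the most common alternate allele is retained
#'   and calls carrying any other alternate become missing.
#' * When a GP field (genotype probabilities, biallelic triplet) is present,
#'   a call is emitted only if its largest probability reaches
#'   `hard_call_threshold`; otherwise the call is missing.
#' * Haploid or half-missing GT entries become missing calls.
#'
#' After import, a1 is the lower-frequency allele (ties resolved toward the
#' alternate allele); sample phenotypes are set to the missing code -9.
#'
#' @param path VCF file path (`.vcf` or `.vcf.gz`).
#' @param biallelic_only skip variants with more than one alternate allele.
#' @param hard_call_threshold minimum genotype probability for a hard call
#'   when GP is present (default 0.9).
#' @return A [new_dataset()] object.
#' @export
import_vcf <- function(path, biallelic_only = FALSE, hard_call_threshold = 0.9) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L)
    stop("not a VCF: #CHROM header line missing or duplicated")
  header <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10L)
    stop("VCF has no sample columns")
  sample_ids <- header[-(1:9)]
  n <- length(sample_ids)
  body_idx <- seq(hdr + 1L, length.out = length(lines) - hdr)
  body_idx <- body_idx[nzchar(lines[body_idx])]
  rows <- vector("list", length(body_idx))
  keep <- logical(length(body_idx))
  vinfo <- vector("list", length(body_idx))
  for (r in seq_along(body_idx)) {
    lno <- body_idx[r]
    f <- strsplit(lines[lno], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L + n)
      stop(sprintf("malformed VCF line %d: %d fields, %d expected",
                   lno, length(f), 9L + n))
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i))
      stop(sprintf("VCF line %d: no GT field in FORMAT", lno))
    gp_i <- match("GP", fmt)
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1L && biallelic_only) next
    calls <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    gts <- vapply(calls, function(x) x[gt_i], character(1))
    allele_lists <- strsplit(gts, "[/|]")
    if (length(alts) > 1L) {
      # retain the most common alternate; other alternates become missing
      all_codes <- suppressWarnings(as.integer(unlist(allele_lists)))
      tab <- tabulate(all_codes[!is.na(all_codes) & all_codes >= 1L],
                      nbins = length(alts))
      alt_keep <- which.max(tab) # ties -> lowest-numbered alternate
    } else alt_keep <- 1L
    alt_allele <- alts[alt_keep]
    dos <- vapply(seq_len(n), function(i) {
      al <- suppressWarnings(as.integer(allele_lists[[i]]))
      if (length(al) != 2L || anyNA(al)) return(NA_integer_)
      if (any(!(al %in% c(0L, alt_keep)))) return(NA_integer_)
      sum(al == alt_keep)
    }, integer(1))
    if (!is.na(gp_i)) {
      for (i in seq_len(n)) {
        gp_s <- calls[[i]][gp_i]
        if (is.na(gp_s) || gp_s == "." || !nzchar(gp_s)) next
        gp <- suppressWarnings(as.numeric(strsplit(gp_s, ",", fixed = TRUE)[[1]]))
        if (length(gp) != 3L || anyNA(gp)) next # not a biallelic triplet
        if (max(gp) >= hard_call_threshold) dos[i] <- which.max(gp) - 1L
        else dos[i] <- NA_integer_
      }
    }
    keep[r] <- TRUE
    rows[[r]] <- dos
    vid <- f[3]
    if (vid == ".") vid <- paste0(f[1], ":", f[2])
    vinfo[[r]] <- list(chrom = f[1], vid = vid, bp = as.integer(f[2]),
                       ref = f[4], alt = alt_allele)
  }
  rows <- rows[keep]
  vinfo <- vinfo[keep]
  m <- length(rows)
  geno <- matrix(NA_integer_, n, m) # alt dosage for now
  for (j in seq_len(m)) geno[, j] <- rows[[j]]
  # a1 = lower-frequency allele; ties -> the alternate allele
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    d <- geno[, j]
    alt_count <- sum(d, na.rm = TRUE)
    obs <- 2L * sum(!is.na(d))
    ref_count <- obs - alt_count
    if (alt_count <= ref_count) {
      a1[j] <- vinfo[[j]]$alt; a2[j] <- vinfo[[j]]$ref
      geno[, j] <- 2L - d # stored dosage counts a2 = REF
    } else {
      a1[j] <- vinfo[[j]]$ref; a2[j] <- vinfo[[j]]$alt
    }
  }
  variants <- data.frame(
    chrom = vapply(vinfo, `[[`, character(1), "chrom"),
    vid = vapply(vinfo, `[[`, character(1), "vid"),
    cm = rep(0, m),
    bp = vapply(vinfo, `[[`, integer(1), "bp"),
    a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  samples <- data.frame(
    fid = sample_ids, iid = sample_ids, pid = "0", mid = "0",
    sex = 0L, phenotype = -9, stringsAsFactors = FALSE)
  new_dataset(pack_genotypes(geno), samples, variants)
}
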