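test_that("packing a genotype matrix and unpacking it is the identity", {
  set.seed(101)
  for (dims in list(c(1, 1), c(4, 3), c(5, 2), c(17, 5), c(64, 10))) {
    g <- matrix(random_genotypes(prod(dims)), dims[1], dims[2])
    pk <- pack_genotypes(g)
    expect_identical(unpack_genotypes(pk), g)
    expect_equal(length(pk$data), ceiling(dims[1] / 4) * dims[2])
  }
})

test_that("bed round trip reproduces genotypes and tables bit for bit", {
  set.seed(102)
  sim <- simulate_dataset(sim_spec(17, 5, missing_rate = 0.2, seed = 5))
  ds <- sim$dataset
  prefix <- file.path(tempdir(), "rt")
  write_bed(ds, prefix)
  ds2 <- read_bed(prefix = prefix)
  expect_identical(ds2$genotypes$data, ds$genotypes$data)
  expect_identical(ds2$samples$iid, ds$samples$iid)
  expect_identical(ds2$samples$phenotype, ds$samples$phenotype)
  expect_identical(ds2$variants$vid, ds$variants$vid)
  expect_identical(ds2$variants$bp, ds$variants$bp)
  expect_identical(ds2$variants$a1, ds$variants$a1)
})

test_that("bed payload layout follows the documented 2-bit dialect", {
  # byte 0b00001110: sample 1 in low bits = 10 (het), sample 2 = 11 (hom a2)
  g <- matrix(c(1L, 2L), 2, 1)
  pk <- pack_genotypes(g)
  expect_identical(pk$data, as.raw(0x0e)) # pads are 00
  # 5 samples -> ceil(5/4) = 2 bytes per variant
  expect_equal(length(pack_genotypes(matrix(0L, 5, 3))$data), 6)
  # empty dataset -> .bed is exactly the 3 header bytes
  ds0 <- new_dataset(matrix(integer(0), 4, 0))
  prefix <- file.path(tempdir(), "empty")
  write_bed(ds0, prefix)
  expect_equal(file.size(paste0(prefix, ".bed")), 3)
})

test_that("malformed bed files are rejected with specific errors", {
  prefix <- file.path(tempdir(), "bad")
  ds <- new_dataset(matrix(c(0L, 1L, 2L, NA), 2, 2))
  write_bed(ds, prefix)
  bed <- paste0(prefix, ".bed")
  raw <- readBin(bed, "raw", file.size(bed))
  # sample-major mode byte
  writeBin(c(raw[1:2], as.raw(0), raw[-(1:3)]), bed)
  expect_error(read_bed(prefix = prefix), "sample-major unsupported")
  # bad magic
  writeBin(c(as.raw(c(1, 2)), raw[-(1:2)]), bed)
  expect_error(read_bed(prefix = prefix), "magic")
  # truncation
  writeBin(raw[-length(raw)], bed)
  expect_error(read_bed(prefix = prefix), "truncated")
})

test_that("allele frequencies match a per-call counting loop", {
  set.seed(103)
  ds <- random_dataset(23, 11, missing_rate = 0.15, seed = 7)
  fr <- allele_frequencies(ds)
  G <- unpack_genotypes(ds)
  for (j in seq_len(ncol(G))) {
    x <- G[, j]
    a1 <- sum(2 - x, na.rm = TRUE)
    obs <- 2 * sum(!is.na(x))
    expect_equal(fr$a1_count[j], a1)
    expect_equal(fr$obs_allele_count[j], obs)
    if (obs > 0) expect_equal(fr$a1_freq[j], a1 / obs)
  }
  # monomorphic and symmetric cases
  expect_equal(allele_frequencies(new_dataset(matrix(2L, 10, 1)))$maf, 0)
  expect_equal(allele_frequencies(new_dataset(matrix(0L, 10, 1)))$maf, 0)
  expect_equal(allele_frequencies(new_dataset(matrix(c(0L, 1L, 2L), 3, 1)))$maf, 0.5)
  fr0 <- allele_frequencies(new_dataset(matrix(NA_integer_, 4, 1)))
  expect_true(fr0$all_missing)
  expect_true(is.na(fr0$maf))
})

test_that("pad bits beyond the last sample never affect results", {
  set.seed(104)
  ds <- random_dataset(13, 8, missing_rate = 0.1, seed = 3) # 3 pad calls
  ds2 <- ds
  raw <- as.integer(ds2$genotypes$data)
  bpv <- ceiling(13 / 4)
  # force all pad calls (top 3 slots of each row's last byte) to hom a2
  for (j in seq_len(8)) {
    b <- raw[j * bpv]
    raw[j * bpv] <- bitwAnd(b, 3L) + 252L # 11 11 11 in the pad slots
  }
  ds2$genotypes$data <- as.raw(raw)
  expect_equal(allele_frequencies(ds2), allele_frequencies(ds))
  expect_equal(ibs_matrix(ds2)$ibs, ibs_matrix(ds)$ibs)
  expect_equal(grm(ds2)$values, grm(ds)$values)
  expect_equal(pair_r(ds2, c(1, 2))$r, pair_r(ds, c(1, 2))$r)
})

write_vcf_lines <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

test_that("VCF import discards phase and applies the GP hard-call rule", {
  path <- write_vcf_lines(c(
    vcf_header(c("s1", "s2", "s3")),
    "1\t100\trs1\tA\tC\t.\t.\t.\tGT\t0|1\t0/1\t1/1",
    "1\t200\trs2\tG\tT\t.\t.\t.\tGT:GP\t0/0:0.95,0.04,0.01\t0/1:0.5,0.4,0.1\t1/1:0.02,0.03,0.95"))
  ds <- import_vcf(path)
  G <- unpack_genotypes(ds)
  # rs1: both het calls identical regardless of separator
  expect_equal(G[1, 1], G[2, 1])
  expect_equal(G[1, 1], 1L)
  # rs2: middle sample fails the 0.9 hard-call threshold
  expect_true(is.na(G[2, 2]))
  expect_false(is.na(G[1, 2]))
  expect_false(is.na(G[3, 2]))
  # importing twice gives identical datasets
  ds2 <- import_vcf(path)
  expect_identical(ds$genotypes$data, ds2$genotypes$data)
})

test_that("multi-allelic sites keep the most common alternate or are skipped", {
  lines <- c(
    vcf_header(c("s1", "s2", "s3", "s4", "s5", "s6", "s7")),
    paste0("1\t300\trs3\tA\tC,T\t.\t.\t.\tGT\t",
           paste(c("0/1", "0/1", "1/1", "0/2", "0/2", "0/0", "0/0"),
                 collapse = "\t")))
  ds <- import_vcf(write_vcf_lines(lines))
  G <- unpack_genotypes(ds)
  # C has 4 copies, T has 2: T carriers become missing
  expect_true(all(is.na(G[4:5, 1])))
  expect_false(anyNA(G[c(1:3, 6:7), 1]))
  expect_true("C" %in% c(ds$variants$a1, ds$variants$a2))
  ds2 <- import_vcf(write_vcf_lines(lines), biallelic_only = TRUE)
  expect_equal(dim(ds2)[2], 0)
})

test_that("VCF structural problems raise errors with line numbers", {
  bad <- write_vcf_lines(c(vcf_header("s1"), "1\t100\trs1\tA\tC\t.\t."))
  expect_error(import_vcf(bad), "line 3")
  nogt <- write_vcf_lines(c(vcf_header("s1"),
                            "1\t100\trs1\tA\tC\t.\t.\t.\tDP\t12"))
  expect_error(import_vcf(nogt), "GT")
})

test_that("a1 is assigned the minor allele on import, ties to ALT", {
  path <- write_vcf_lines(c(
    vcf_header(c("s1", "s2")),
    "1\t100\tv1\tA\tC\t.\t.\t.\tGT\t1/1\t0/1", # ALT major -> a1 = REF
    "1\t200\tv2\tA\tC\t.\t.\t.\tGT\t0/1\t0/1")) # tie -> a1 = ALT
  ds <- import_vcf(path)
  expect_equal(ds$variants$a1, c("A", "C"))
  expect_equal(ds$variants$a2, c("C", "A"))
  fr <- allele_frequencies(ds)
  expect_true(all(fr$a1_freq <= 0.5))
})
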