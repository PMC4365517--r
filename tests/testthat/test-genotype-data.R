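test_that("genotype matrix validates calls and ids", {
  expect_error(genotype_matrix(matrix(c(0, 1, 3), 1)), "0, 1 or 2")
  expect_error(genotype_matrix(matrix(0:1, 2, 2),
                               sample_ids = c("a", "a")), "duplicate")
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, 2L), 2, 2))
  expect_s3_class(g, "genotype_matrix")
  expect_identical(dim(g), c(2L, 2L))
})

test_that("VCF genotypes are read as ALT-allele counts", {
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
           "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
           "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1\t1|1")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  g <- read_genotypes(f)
  expect_identical(unname(unclass(g)[, "v1"]), c(0L, 1L, 2L))
  expect_identical(unname(unclass(g)[, "v2"]), c(0L, 1L, 2L))
  expect_identical(rownames(g), c("S1", "S2", "S3"))
})

test_that("multi-allelic VCF records are skipped with a warning", {
  rec <- function(pos, id, alt, gts) paste0("1\t", pos, "\t", id, "\tA\t", alt,
                                            "\t.\tPASS\t.\tGT\t", gts)
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
           rec(1, "v1", "G", "0/0\t0/1"),
           rec(2, "v2", "G,T", "0/0\t1/2"),
           rec(3, "v3", "G", "1/1\t0/1"),
           rec(4, "v4", "C", "0/0\t0/0"),
           rec(5, "v5", "T", "0/1\t0/1"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_warning(g <- read_genotypes(f), "multi-allelic")
  expect_identical(ncol(g), 4L)
  expect_false("v2" %in% colnames(g))
})

test_that("missing-genotype policies behave as documented", {
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
           "1\t1\tv1\tA\tG\t.\t.\t.\tGT\t0/0\t./.\t1/1",
           "1\t2\tv2\tA\tG\t.\t.\t.\tGT\t0/1\t0/0\t1/1")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_error(read_genotypes(f, missing_policy = "fail"), "v1")
  expect_message(g1 <- read_genotypes(f, missing_policy = "drop_variant"),
                 "dropped")
  expect_identical(colnames(g1), "v2")
  expect_message(g2 <- read_genotypes(f, missing_policy = "mean_impute"),
                 "imputed")
  expect_identical(unname(unclass(g2)[2, "v1"]), 1L) # mean(0,2) = 1
})

test_that("plain matrix format round-trips and rejects bad calls", {
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, 2L, 1L, 0L), 3, 2),
                       sample_ids = c("a", "b", "c"),
                       variant_ids = c("v1", "v2"),
                       chrom = c("1", "2"), pos = c(10L, 20L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, f)
  g2 <- read_genotypes(f, format = "matrix")
  expect_identical(unclass(g2), unclass(g))
  expect_identical(attr(g2, "variants")$pos, c(10L, 20L))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\ta\tb", "v1\t3\t0"), f2)
  expect_error(read_genotypes(f2, format = "matrix"), "invalid genotype call")
})

test_that("variant stats match direct column computations", {
  g <- gm(c(0L, 1L, 2L), c(0L, 0L, 0L), c(2L, 2L, 1L))
  vs <- variant_stats(g)
  expect_equal(vs$p, c(0.5, 0, 5 / 6))
  expect_equal(vs$maf, c(0.5, 0, 1 / 6))
  expect_identical(vs$mac, c(3L, 0L, 1L))
  expect_identical(vs$n_obs, rep(3L, 3))
})

test_that("two minor copies in 118 diploids fall below the 1% MAF cut", {
  calls <- c(rep(0L, 116L), 1L, 1L)
  g <- genotype_matrix(matrix(calls, ncol = 1))
  vs <- variant_stats(g)
  expect_equal(vs$maf, 2 / 236)
  expect_lt(vs$maf, 0.01)
  expect_identical(ncol(suppressWarnings(apply_maf_scenario(g, "1+"))), 0L)
})

test_that("variant stats are orientation- and order-invariant where claimed", {
  set.seed(11)
  g <- genotype_matrix(matrix(sample(0:2, 60, TRUE), 10, 6))
  flipped <- genotype_matrix(2L - unclass(g))
  vs <- variant_stats(g); vf <- variant_stats(flipped)
  expect_equal(vf$p, 1 - vs$p)
  expect_equal(vf$maf, vs$maf)
  expect_identical(vf$mac, vs$mac)
  shuffled <- genotype_matrix(unclass(g)[sample(10), ])
  expect_equal(variant_stats(shuffled)$p, vs$p)
})

test_that("MAF scenarios use half-open intervals and partition exactly", {
  # maf values 0.004, 0.03, 0.20 plus exact boundaries 0.01, 0.05 and 0.5
  n <- 250L
  mafs <- c(0.004, 0.03, 0.20, 0.01, 0.05, 0.5)
  calls <- vapply(mafs, function(m) {
    k <- round(2 * n * m)
    c(rep(1L, k), rep(0L, 2L * n - k))[seq_len(n) * 2 - 1] +
      c(rep(1L, k), rep(0L, 2L * n - k))[seq_len(n) * 2]
  }, integer(n))
  g <- genotype_matrix(calls)
  vs <- variant_stats(g)
  expect_equal(vs$maf, mafs)
  ids <- function(x) attr(x, "variants")$variant_id
  k15 <- ids(apply_maf_scenario(g, "1_5"))
  k5 <- ids(apply_maf_scenario(g, "5+"))
  k1 <- ids(apply_maf_scenario(g, "1+"))
  expect_setequal(k1, union(k5, k15))
  expect_length(intersect(k5, k15), 0)
  # boundary: maf exactly 0.05 goes to 5+, not 1_5
  v5 <- colnames(g)[vs$maf == 0.05]
  expect_true(v5 %in% k5)
  expect_false(v5 %in% k15)
  # maf = 0.5 kept at the inclusive top; monomorphic variants never pass
  expect_true(colnames(g)[vs$maf == 0.5] %in% k5)
  log <- attr(apply_maf_scenario(g, "1_5"), "filter_log")
  expect_identical(log$kept + log$removed, ncol(g))
})

test_that("scenario partition holds on random simulated matrices", {
  for (seed in 1:5) {
    freqs <- draw_frequency_spectrum(300, "l_shaped", maf_min = 0.005,
                                     seed = seed)
    set.seed(seed + 100)
    g <- genotype_matrix(
      matrix(stats::rbinom(40 * 300, 2, rep(freqs, each = 40)), 40, 300))
    ids <- function(x) attr(x, "variants")$variant_id
    k15 <- ids(suppressWarnings(apply_maf_scenario(g, "1_5")))
    k5 <- ids(suppressWarnings(apply_maf_scenario(g, "5+")))
    k1 <- ids(suppressWarnings(apply_maf_scenario(g, "1+")))
    expect_setequal(k1, c(k5, k15))
    expect_length(intersect(k5, k15), 0)
  }
})

test_that("chip subsetting is a set operation preserving order", {
  g <- genotype_matrix(matrix(0:1, 4, 5), variant_ids = paste0("v", 1:5))
  out <- subset_chip(g, c("v4", "v2"))
  expect_identical(colnames(out), c("v2", "v4")) # original order
  expect_warning(empty <- subset_chip(g, character(0)), "no listed")
  expect_identical(ncol(empty), 0L)
  expect_message(dup <- subset_chip(g, c("v1", "v1", "vX")), "1 listed id")
  expect_identical(colnames(dup), "v1")
  expect_identical(attr(dup, "ids_not_found"), "vX")
})
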