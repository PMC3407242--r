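write_ped_fixture <- function(ped_rows, map_rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  writeLines(ped_rows, ped)
  writeLines(map_rows, map)
  c(ped = ped, map = map)
}

test_that("PED alleles are assigned first-seen and codes count allele_b", {
  f <- write_ped_fixture(
    c("F1 s1 0 0 0 -9 A A", "F2 s2 0 0 0 -9 A G"),
    "1 snp1 0 1000")
  res <- read_ped_map(f["ped"], f["map"])
  expect_equal(unname(res$genotypes$codes[, "snp1"]), c(0L, 1L))
  expect_equal(res$map$allele_a, "A")
  expect_equal(res$map$allele_b, "G")
})

test_that("MAP accepts X as a chromosome label and sorts by position", {
  f <- write_ped_fixture(
    "F1 s1 0 0 0 -9 A A C C G G",
    c("1 snpB 0 2000", "1 snpA 0 1000", "X snpX 0 500"))
  res <- read_ped_map(f["ped"], f["map"])
  expect_equal(nrow(res$map), 3)
  expect_equal(res$map$snp_id, c("snpA", "snpB", "snpX"))
  expect_equal(res$map$chromosome, c("1", "1", "X"))
})

test_that("missing and malformed PED entries are rejected with location", {
  f <- write_ped_fixture(
    c("F1 s1 0 0 0 -9 A A", "F2 s2 0 0 0 -9 A"),
    "1 snp1 0 1000")
  expect_error(read_ped_map(f["ped"], f["map"]), "line 2")

  f2 <- write_ped_fixture(
    c("F1 s1 0 0 0 -9 A C", "F2 s2 0 0 0 -9 G G"),
    "1 snp1 0 1000")
  expect_error(read_ped_map(f2["ped"], f2["map"]), "snp1")

  f3 <- write_ped_fixture(
    "F1 s1 0 0 0 -9 A 0",
    "1 snp1 0 1000")
  expect_error(read_ped_map(f3["ped"], f3["map"]), "allele 0")
})

test_that("read-write-read is the identity on codes and map", {
  # start from a file: the reader's first-seen allele assignment is then a
  # fixed point, so a write/read cycle must reproduce codes and map exactly
  set.seed(42)
  codes <- matrix(sample(c(0:2, NA), 5 * 20, replace = TRUE), 5, 20)
  g <- make_geno(codes, chrom = sample(c("1", "2", "X"), 20, replace = TRUE))
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_ped_map(g, prefix)
  r1 <- read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map"))

  prefix2 <- file.path(withr::local_tempdir(), "rt2")
  write_ped_map(r1$genotypes, prefix2)
  r2 <- read_ped_map(paste0(prefix2, ".ped"), paste0(prefix2, ".map"))
  expect_identical(r2$genotypes$codes, r1$genotypes$codes)
  expect_equal(r2$map, r1$map)
  # the two files carry identical unordered genotype letter pairs
  pairs_of <- function(path) {
    lapply(strsplit(readLines(path), "\t"), function(f) {
      m <- matrix(f[-(1:6)], nrow = 2)
      apply(m, 2, function(p) paste(sort(p), collapse = ""))
    })
  }
  expect_identical(pairs_of(paste0(prefix2, ".ped")),
                   pairs_of(paste0(prefix, ".ped")))
})

test_that("degenerate PED writes are valid", {
  g <- make_geno(matrix(NA_integer_, 1, 3))
  prefix <- file.path(withr::local_tempdir(), "allmiss")
  write_ped_map(g, prefix)
  fields <- strsplit(readLines(paste0(prefix, ".ped")), "\t")[[1]]
  expect_equal(fields[7:12], rep("0", 6))
  back <- read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_true(all(is.na(back$genotypes$codes)))
})

test_that("QC with zero thresholds is the identity", {
  set.seed(1)
  g <- make_geno(matrix(sample(c(0:2, NA), 200, replace = TRUE), 10, 20))
  res <- apply_qc(g, 0, 0, 0)
  expect_identical(res$genotypes$codes, g$codes)
  expect_equal(sum(res$report$n_removed), 0)
})

test_that("MAF filter removes exactly the monomorphic SNPs", {
  set.seed(2)
  codes <- matrix(sample(0:2, 80, replace = TRUE, prob = c(.3, .4, .3)), 8, 10)
  codes[, 3] <- 0L
  codes[, 7] <- 2L
  g <- make_geno(codes)
  res <- apply_qc(g, maf_min = 0.01)
  expect_equal(attr(res$report, "n_snps_removed"), 2)
  expect_false(any(c("snp3", "snp7") %in% res$genotypes$map$snp_id))
})

test_that("SNP call-rate removals match a brute-force per-column tally", {
  set.seed(3)
  codes <- matrix(sample(0:2, 20 * 500, replace = TRUE), 20, 500)
  codes[sample(length(codes), round(0.05 * length(codes)))] <- NA
  g <- make_geno(codes)
  res <- apply_qc(g, snp_call_rate_min = 0.99)
  brute <- sum(vapply(seq_len(500), function(l) {
    mean(!is.na(codes[, l])) < 0.99
  }, logical(1)))
  expect_equal(attr(res$report, "n_snps_removed"), brute)
})

test_that("QC is idempotent and an emptied panel errors", {
  set.seed(4)
  codes <- matrix(sample(c(0:2, NA), 600, replace = TRUE), 12, 50)
  g <- make_geno(codes)
  once <- apply_qc(g, 0.8, 0.8, 0.05)
  twice <- apply_qc(once$genotypes, 0.8, 0.8, 0.05)
  expect_identical(twice$genotypes$codes, once$genotypes$codes)
  expect_equal(sum(twice$report$n_removed), 0)

  mono <- make_geno(matrix(0L, 5, 4))
  expect_error(apply_qc(mono, maf_min = 0.01), "empty panel")
})

test_that("allele frequency flips to 1 - p under allele label swap", {
  set.seed(5)
  codes <- matrix(sample(0:2, 60, replace = TRUE), 6, 10)
  g <- make_geno(codes)
  swapped <- geno_matrix(2L - g$codes,
                         dplyr::mutate(g$map,
                                       tmp = allele_a,
                                       allele_a = allele_b,
                                       allele_b = tmp)[, names(g$map)])
  expect_equal(allele_freq(swapped), 1 - allele_freq(g))
})
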