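test_that("a fixed difference gives per-SNP F_ST of exactly 1", {
  codes <- rbind(a1 = 0L, a2 = 0L, b1 = 2L, b2 = 2L)
  g <- make_geno(codes)
  labs <- two_pop_labels(g, 2)
  comp <- fst_components(g, labs, c("A", "B"))
  expect_equal(comp$num, 1)
  expect_equal(comp$den, 1)
  expect_equal(comp$fst, 1)
  expect_equal(global_fst(comp), 1)
})

test_that("equal intermediate frequencies give the small-sample negative bias", {
  # p = 0.5 in both populations, 50 chromosomes each
  one_pop <- c(rep(0L, 12), rep(2L, 12), 1L)
  g <- make_geno(matrix(c(one_pop, one_pop), ncol = 1))
  labs <- two_pop_labels(g, 25)
  comp <- fst_components(g, labs, c("A", "B"))
  expect_equal(comp$num, -2 * 0.25 / 49, tolerance = 1e-12)
  expect_equal(comp$den, 0.5)
  expect_equal(comp$fst, -0.0204, tolerance = 1e-3)
})

test_that("components equal a brute-force recomputation from raw codes", {
  set.seed(51)
  codes <- matrix(sample(c(0:2, NA), 20 * 80, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), 20, 80)
  g <- make_geno(codes)
  labs <- two_pop_labels(g, 9)
  comp <- fst_components(g, labs, c("A", "B"))
  brute <- brute_fst_components(g, labs, c("A", "B"))
  expect_equal(comp$snp_id, brute$snp_id)
  expect_equal(comp$num, brute$num)
  expect_equal(comp$den, brute$den)
})

test_that("monomorphic SNPs are flagged uninformative and excluded", {
  codes <- cbind(rep(0L, 8), c(rep(0L, 4), rep(2L, 4)))
  g <- make_geno(codes)
  labs <- two_pop_labels(g, 4)
  comp <- fst_components(g, labs, c("A", "B"))
  expect_false(comp$informative[1])
  expect_true(comp$informative[2])
  expect_equal(global_fst(comp), 1)
})

test_that("a randomly split population has near-zero global F_ST", {
  sim <- simulate_balding_nichols(n_pops = 1, drift = 0.05, n_snps = 5000,
                                  samples_per_pop = 40, seed = 52)
  ids <- sample_ids(sim$genotypes)
  set.seed(53)
  half <- sample(ids, 20)
  labs <- pop_labels(ids, ifelse(ids %in% half, "A", "B"))
  fst <- global_fst(fst_components(sim$genotypes, labs, c("A", "B")))
  expect_lt(abs(fst), 0.01)
})

test_that("F_ST is invariant to swapping the populations and to SNP order", {
  set.seed(54)
  codes <- matrix(sample(0:2, 16 * 60, replace = TRUE), 16, 60)
  g <- make_geno(codes)
  labs <- two_pop_labels(g, 8)
  ab <- fst_components(g, labs, c("A", "B"))
  ba <- fst_components(g, labs, c("B", "A"))
  expect_equal(global_fst(ab), global_fst(ba))
  expect_equal(ab$fst, ba$fst)

  shuf <- subset_geno(g, snps = sample(g$map$snp_id))
  expect_equal(global_fst(fst_components(shuf, labs, c("A", "B"))),
               global_fst(ab))
})

test_that("ratio-of-sums global F_ST ignores SNP duplication", {
  set.seed(55)
  codes <- matrix(sample(0:2, 10 * 40, replace = TRUE), 10, 40)
  g <- make_geno(codes)
  labs <- two_pop_labels(g, 5)
  doubled <- make_geno(cbind(codes, codes))
  expect_equal(global_fst(fst_components(doubled, labs, c("A", "B"))),
               global_fst(fst_components(g, labs, c("A", "B"))))
})

test_that("bootstrap SD is 0 for identical loci and matches a 2-locus closed form", {
  comp1 <- tibble::tibble(num = rep(0.2, 30), den = rep(0.5, 30),
                          informative = TRUE)
  expect_equal(bootstrap_sd(comp1, 100, seed = 1), 0)

  # two loci: resamples are (1,1), (1,2), (2,1), (2,2) with equal chance;
  # the ratio takes value n1/d1, (n1+n2)/(d1+d2), n2/d2 with prob 1/4,1/2,1/4
  n <- c(0.3, 0.1); d <- c(0.5, 0.8)
  vals <- c(n[1] / d[1], sum(n) / sum(d), n[2] / d[2])
  pr <- c(0.25, 0.5, 0.25)
  mu <- sum(vals * pr)
  sigma <- sqrt(sum(pr * (vals - mu)^2))
  comp2 <- tibble::tibble(num = n, den = d, informative = TRUE)
  est <- bootstrap_sd(comp2, 4000, seed = 2)
  expect_lt(abs(est - sigma) / sigma, 0.1)
})

test_that("bootstrap SD roughly halves when the panel is duplicated 4x", {
  set.seed(56)
  comp <- tibble::tibble(num = rnorm(200, 0.05, 0.03),
                         den = runif(200, 0.2, 0.6), informative = TRUE)
  big <- tibble::tibble(num = rep(comp$num, 4), den = rep(comp$den, 4),
                        informative = TRUE)
  r <- bootstrap_sd(comp, 500, seed = 3) / bootstrap_sd(big, 500, seed = 4)
  expect_lt(abs(r - 2), 0.5)
})

test_that("pairwise matrix covers all unordered pairs and orders by drift", {
  sim <- simulate_balding_nichols(n_pops = 6, drift = 0.05, n_snps = 200,
                                  samples_per_pop = 8, seed = 57)
  m <- pairwise_fst_matrix(sim$genotypes, sim$labels, n_boot = 20, seed = 58)
  expect_equal(nrow(m), 15)
  tab <- render_fst_table(m)
  expect_equal(dim(tab), c(6, 6))
  expect_equal(diag(tab), setNames(rep(0, 6), paste0("P", 1:6)))

  wins <- 0
  for (r in 1:10) {
    s3 <- simulate_balding_nichols(n_pops = 3, drift = c(0.02, 0.02, 0.10),
                                   n_snps = 500, samples_per_pop = 15,
                                   seed = 300 + r)
    p <- pairwise_fst_matrix(s3$genotypes, s3$labels, n_boot = 2, seed = r)
    low <- p$fst[p$pop1 == "P1" & p$pop2 == "P2"]
    if (low == min(p$fst)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("populations with one sample are skipped with a warning", {
  codes <- matrix(sample(0:2, 5 * 30, replace = TRUE), 5, 30)
  g <- make_geno(codes)
  labs <- pop_labels(sample_ids(g), c("A", "A", "B", "B", "C"))
  expect_warning(m <- pairwise_fst_matrix(g, labs, n_boot = 5, seed = 1),
                 "C")
  expect_equal(nrow(m), 1)
})

test_that("top-fraction selection uses the ceiling rule", {
  set.seed(59)
  big <- tibble::tibble(snp_id = sprintf("s%05d", 1:49034),
                        fst = runif(49034))
  expect_length(rank_top_fraction(big, 0.01), 491)
  small <- tibble::tibble(snp_id = paste0("s", 1:100), fst = runif(100))
  expect_length(rank_top_fraction(small, 0.05), 5)
})

test_that("ranking matches a brute-force sort with snp_id tie-break", {
  set.seed(60)
  fst <- sample(round(runif(200), 2), 200, replace = TRUE)
  tbl <- tibble::tibble(snp_id = paste0("s", sample(200)), fst = fst)
  got <- rank_top_fraction(tbl, 0.1)
  ord <- tbl[order(-tbl$fst, tbl$snp_id), ]
  expect_equal(got, ord$snp_id[1:20])
})

test_that("enrichment reproduces the share/ratio arithmetic", {
  # a chromosome holding 3.8% of the panel contributing 9.2% of top SNPs
  chrom <- c(rep("10", 38), rep("1", 962))
  map <- snp_map(paste0("s", 1:1000), chrom, 1:1000, "A", "G")
  top <- c(paste0("s", 1:23), paste0("s", 39:265))   # 250 top, 23 on chr10
  enr <- chromosome_enrichment(top, map)
  r10 <- enr[enr$chromosome == "10", ]
  expect_equal(r10$expected_fraction, 0.038)
  expect_equal(r10$observed_fraction, 0.092)
  expect_equal(r10$ratio, 2.42, tolerance = 0.01)
  expect_equal(sum(enr$observed_fraction), 1)
  expect_equal(sum(enr$expected_fraction), 1)
})

test_that("hypergeometric p equals exhaustive enumeration on a toy panel", {
  map <- snp_map(paste0("s", 1:20), c(rep("1", 8), rep("2", 12)),
                 1:20, "A", "G")
  top <- paste0("s", c(1:4, 9))      # 4 of 5 top SNPs on chromosome 1
  enr <- chromosome_enrichment(top, map)
  subsets <- utils::combn(20, 5)
  on_chr1 <- colSums(subsets <= 8)
  expect_equal(enr$p_value[enr$chromosome == "1"], mean(on_chr1 >= 4))
  expect_equal(enr$p_value[enr$chromosome == "2"], mean((5 - on_chr1) >= 1))
})

test_that("uniformly drawn top sets show no systematic enrichment", {
  map <- snp_map(paste0("s", 1:400),
                 rep(as.character(1:8), each = 50), 1:400, "A", "G")
  set.seed(61)
  ratios <- replicate(100, {
    enr <- chromosome_enrichment(paste0("s", sample(400, 40)), map)
    mean(enr$ratio)
  })
  expect_lt(abs(mean(ratios) - 1), 0.05)
  set.seed(62)
  rejections <- mean(replicate(200, {
    enr <- chromosome_enrichment(paste0("s", sample(400, 40)), map)
    enr$p_value[1] < 0.05
  }))
  expect_lte(rejections, 0.09)
})
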