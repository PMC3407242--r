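test_that("fully homozygous samples resolve in direct gamete counts", {
  codes <- rbind(s1 = c(2L, 2L), s2 = c(0L, 0L), s3 = c(2L, 0L))
  g <- make_geno(codes)
  res <- em_haplotype_frequencies(g, c("snp1", "snp2"),
                                  settings = em_settings(n_restarts = 1))
  # gametes: 2x GG, 2x AA, 2x GA (allele_a = A, allele_b = G)
  expect_equal(res$freq[["GG"]], 1 / 3)
  expect_equal(res$freq[["AA"]], 1 / 3)
  expect_equal(res$freq[["GA"]], 1 / 3)
  expect_equal(res$n_used, 3)
  expect_true(res$converged)
})

test_that("EM attains the exhaustive-grid maximum on the ambiguous 2-SNP instance", {
  # one individual homozygous b/b at both SNPs, one double heterozygote
  codes <- rbind(s1 = c(2L, 2L), s2 = c(1L, 1L))
  g <- make_geno(codes)
  res <- em_haplotype_frequencies(g, c("snp1", "snp2"))
  oracle <- grid_oracle_2snp(0.001)
  expect_equal(res$log_likelihood, unname(oracle["ll"]), tolerance = 1e-5)
  expect_equal(res$freq[["GG"]], unname(oracle["t"]), tolerance = 1e-3)
  expect_equal(res$freq[["AA"]], unname(oracle["u"]), tolerance = 1e-3)
  # closed form: f_GG = 3/4, f_AA = 1/4
  expect_equal(res$freq[["GG"]], 0.75, tolerance = 1e-6)
  expect_equal(res$freq[["AA"]], 0.25, tolerance = 1e-6)
})

test_that("EM matches an independent likelihood maximiser on tiny instances", {
  # oracle: direct maximisation over the softmax-parameterised simplex,
  # many Nelder-Mead starts, using its own likelihood bookkeeping
  oracle_ll <- function(codes, m) {
    n_hap <- 2^m
    hap_bits <- sapply(0:(n_hap - 1), function(h)
      as.integer(intToBits(h))[1:m])
    ind_ll <- function(f, geno) {
      total <- 0
      for (a in 1:n_hap) for (b in a:n_hap) {
        if (all(hap_bits[, a] + hap_bits[, b] == geno)) {
          total <- total + (if (a == b) f[a]^2 else 2 * f[a] * f[b])
        }
      }
      log(total)
    }
    obj <- function(theta) {
      f <- exp(theta) / sum(exp(theta))
      -sum(apply(codes, 1, function(row) ind_ll(f, row)))
    }
    best <- Inf
    for (s in 1:8) {
      set.seed(s)
      fit <- stats::optim(rnorm(n_hap), obj,
                          control = list(maxit = 3000, reltol = 1e-12))
      best <- min(best, fit$value)
    }
    -best
  }
  set.seed(63)
  for (rep in 1:4) {
    m <- sample(2:3, 1)
    n <- sample(2:4, 1)
    codes <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    g <- make_geno(codes)
    res <- em_haplotype_frequencies(g, paste0("snp", 1:m))
    expect_gte(res$log_likelihood, oracle_ll(codes, m) - 1e-6)
  }
})

test_that("samples with missing window calls are excluded and counted", {
  codes <- rbind(s1 = c(2L, 2L), s2 = c(NA, 1L), s3 = c(0L, 0L))
  g <- make_geno(codes)
  res <- em_haplotype_frequencies(g, c("snp1", "snp2"),
                                  settings = em_settings(n_restarts = 1))
  expect_equal(res$n_used, 2)
  expect_equal(res$n_excluded, 1)
  all_na <- rbind(s1 = c(NA_integer_, NA_integer_))
  expect_error(em_haplotype_frequencies(make_geno(all_na),
                                        c("snp1", "snp2")),
               "complete calls")
})

test_that("EM recovers the generating haplotype vector at reference sample size", {
  sim <- simulate_balding_nichols(
    n_pops = 1, drift = 0.02, n_snps = 20, samples_per_pop = 35,
    chromosomes = data.frame(chromosome = "10", n_snps = 20), seed = 64)
  w <- sim$genotypes$map$snp_id[1:4]
  blk <- poll_block(w, c(P1 = "Florida Native"))
  inj <- inject_haplotype_block(sim$genotypes, sim$labels, sim$truth, blk,
                                seed = 65)
  res <- em_haplotype_frequencies(inj$genotypes, w)
  named <- poll_window()$named
  target <- c(H1 = 0.49, H2 = 0.03, H3 = 0.39)
  for (h in names(target)) {
    se <- sqrt(max(target[[h]], 0.01) * (1 - target[[h]]) / 70)
    expect_lt(abs(res$freq[[named[[h]]]] - target[[h]]), 3 * se + 0.02)
  }
})

test_that("estimates are invariant to sample order and allele relabelling", {
  set.seed(66)
  codes <- matrix(sample(0:2, 12 * 3, replace = TRUE), 12, 3,
                  dimnames = list(paste0("s", 1:12), NULL))
  g <- make_geno(codes)
  w <- paste0("snp", 1:3)
  a <- em_haplotype_frequencies(g, w)
  g_perm <- subset_geno(g, samples = sample(rownames(codes)))
  b <- em_haplotype_frequencies(g_perm, w)
  expect_equal(a$freq, b$freq, tolerance = 1e-6)
  expect_equal(a$log_likelihood, b$log_likelihood, tolerance = 1e-8)

  # swap alleles at the second window SNP: haplotype labels permute
  map2 <- g$map
  i <- match("snp2", map2$snp_id)
  tmp <- map2$allele_a[i]
  map2$allele_a[i] <- map2$allele_b[i]
  map2$allele_b[i] <- tmp
  codes2 <- g$codes
  codes2[, "snp2"] <- 2L - codes2[, "snp2"]
  g_swap <- geno_matrix(codes2, map2)
  c_ <- em_haplotype_frequencies(g_swap, w)
  expect_equal(c_$log_likelihood, a$log_likelihood, tolerance = 1e-6)
  expect_equal(c_$freq[["AGA"]], a$freq[["AGA"]], tolerance = 1e-5)
  expect_equal(c_$freq[["GAG"]], a$freq[["GAG"]], tolerance = 1e-5)
})

test_that("the report renders named rows with a conserved Other column", {
  tabs <- list(X = list(freq = c(GGAA = 1, AGGT = 0, GGAT = 0), n_used = 10))
  named <- c(H1 = "GGAA", H2 = "AGGT", H3 = "GGAT")
  rep1 <- haplotype_report(tabs, named)
  expect_equal(rep1$H1, 1)
  expect_equal(rep1$Other, 0)
  expect_equal(rep1$n_haplotypes, 1)

  # reference vectors render as printed
  fx <- read_poll_fixture()
  lun <- fx[fx$population == "Louisiana Native", ]
  freq <- expand_haplotype_freqs(
    stats::setNames(as.numeric(lun[, c("H1", "H2", "H3")]), unname(named)),
    lun$Other, poll_window()$alphabet)
  rep2 <- haplotype_report(list(`Louisiana Native` = list(freq = freq,
                                                          n_used = 54)),
                           named)
  expect_equal(unlist(rep2[, c("H1", "H2", "H3", "Other")]),
               c(H1 = 0.19, H2 = 0.00, H3 = 0.57, Other = 0.24))

  set.seed(67)
  f <- stats::runif(16)
  f <- f / sum(f)
  names(f) <- names(expand_haplotype_freqs(c(GGAA = 1), 0,
                                           poll_window()$alphabet))
  rep3 <- haplotype_report(list(Z = list(freq = f, n_used = 5)), named)
  expect_lt(abs(rep3$Other - (1 - sum(f[unname(named)]))), 0.011)

  expect_error(haplotype_report(tabs, c(H1 = "GGAA", H1 = "AGGT")),
               "duplicate")
})
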