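#' Gene diversity and proportion of polymorphic SNPs
#'
#' Per SNP, the unbiased (Nei) gene diversity is
#' `He_l = 2 p (1 - p) n / (n - 1)` with `n` the called chromosome count
#' in the population; `He` is its mean over SNPs with `n >= 2` and `Pn`
#' the fraction of SNPs segregating (`0 < p < 1`) within the population.
#'
#' @param g A `geno_matrix`.
#' @param samples Sample ids of the population.
#' @return A list `he`, `pn`, `n_snps_used`.
#' @export
gene_diversity <- function(g, samples) {
  stopifnot(inherits(g, "geno_matrix"))
  if (length(samples) == 0) abort("empty population")
  x <- g$codes[samples, , drop = FALSE]
  n <- 2 * colSums(!is.na(x))
  p <- colSums(x, na.rm = TRUE) / n
  ok <- n >= 2
  he_l <- 2 * p[ok] * (1 - p[ok]) * n[ok] / (n[ok] - 1)
  list(he = mean(he_l),
       pn = mean(p[ok] > 0 & p[ok] < 1),
       n_snps_used = sum(ok))
}

#' Individual inbreeding coefficient
#'
#' Method-of-moments `F = (O_hom - E_hom) / (L - E_hom)` where `O_hom` is
#' the sample's observed homozygous call count, `L` its called SNP count,
#' and `E_hom = sum_l (1 - He_l)` the homozygosity expected under
#' Hardy-Weinberg from the sample's own population frequencies (unbiased
#' `He_l`). Positive values indicate excess homozygosity.
#'
#' @param g A `geno_matrix`.
#' @param sample A sample id.
#' @param pop_samples Sample ids of the population the sample belongs to
#'   (used for the expected homozygosity).
#' @return A single number, or `NA` when the denominator degenerates.
#' @export
inbreeding_f <- function(g, sample, pop_samples) {
  stopifnot(inherits(g, "geno_matrix"))
  xp <- g$codes[pop_samples, , drop = FALSE]
  n <- 2 * colSums(!is.na(xp))
  p <- colSums(xp, na.rm = TRUE) / n
  he_l <- ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), NA_real_)

  xi <- g$codes[sample, ]
  called <- !is.na(xi) & !is.na(he_l)
  l <- sum(called)
  if (l == 0) abort("sample has no usable calls")
  o_hom <- sum(xi[called] != 1L)
  e_hom <- sum(1 - he_l[called])
  if (abs(l - e_hom) < 1e-12) return(NA_real_)
  (o_hom - e_hom) / (l - e_hom)
}

# P(allele with N_i copies of N appears in a rarefied draw of size g),
# and the probability it is absent: C(N - N_i, g) / C(N, g).
rarefied_absence <- function(n_total, n_allele, g) {
  ifelse(n_total - n_allele < g, 0,
         exp(lchoose(n_total - n_allele, g) - lchoose(n_total, g)))
}

#' Rarefied allelic richness and private allelic richness
#'
#' For each SNP and population, the expected number of distinct alleles in
#' a random subsample of `g_copies` allele copies (allelic richness, in
#' `[1, 2]` for biallelic SNPs), and the expected number of those alleles
#' absent from an equally rarefied sample of every other population
#' (private allelic richness). Both are averaged over SNPs. SNPs where any
#' population has fewer than `g_copies` called chromosomes are excluded
#' and counted, so that populations are compared at a common sample size.
#'
#' @param g A `geno_matrix`.
#' @param labels A [pop_labels()] tibble.
#' @param g_copies Rarefaction size in allele copies (>= 1). Default: twice
#'   the smallest population's sample count.
#' @return A tibble: `population`, `ar`, `par`, `n_snps_used`,
#'   `n_snps_excluded`, with `g_copies` as an attribute.
#' @export
allelic_richness <- function(g, labels, g_copies = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  labels <- check_labels(g, labels)
  pops <- unique(labels$population)
  if (is.null(g_copies)) {
    g_copies <- 2 * min(table(labels$population))
  }
  if (g_copies < 1) abort("g_copies must be >= 1")

  # per-pop per-SNP counts of allele b (nb) and total called chromosomes (nn)
  nb <- nn <- matrix(0, length(pops), ncol(g$codes),
                     dimnames = list(pops, colnames(g$codes)))
  for (j in seq_along(pops)) {
    xp <- g$codes[pop_samples(labels, pops[j]), , drop = FALSE]
    nn[j, ] <- 2 * colSums(!is.na(xp))
    nb[j, ] <- colSums(xp, na.rm = TRUE)
  }
  usable <- colSums(nn >= g_copies) == length(pops)
  if (!any(usable)) abort("no SNP has g_copies called chromosomes in every population")

  ar <- par <- setNames(numeric(length(pops)), pops)
  for (j in seq_along(pops)) {
    nbj <- nb[j, usable]; nnj <- nn[j, usable]
    naj <- nnj - nbj
    # presence probabilities for alleles a and b in pop j's rarefied draw
    pres_a <- 1 - rarefied_absence(nnj, naj, g_copies)
    pres_b <- 1 - rarefied_absence(nnj, nbj, g_copies)
    ar[j] <- mean(pres_a + pres_b)
    # absence of each allele from every other population's rarefied draw
    abs_a <- abs_b <- rep(1, sum(usable))
    for (k in seq_along(pops)) {
      if (k == j) next
      nbk <- nb[k, usable]; nnk <- nn[k, usable]
      abs_a <- abs_a * rarefied_absence(nnk, nnk - nbk, g_copies)
      abs_b <- abs_b * rarefied_absence(nnk, nbk, g_copies)
    }
    par[j] <- mean(pres_a * abs_a + pres_b * abs_b)
  }
  out <- tibble(population = pops, ar = unname(ar), par = unname(par),
                n_snps_used = sum(usable),
                n_snps_excluded = sum(!usable))
  structure(out, g_copies = g_copies)
}

#' Per-population diversity report
#'
#' Combines gene diversity, proportion polymorphic, mean individual
#' inbreeding coefficient and rarefied (private) allelic richness into one
#' table, ordered by decreasing gene diversity.
#'
#' @param g A `geno_matrix`.
#' @param labels A [pop_labels()] tibble.
#' @param g_copies Rarefaction size; see [allelic_richness()].
#' @return A tibble: `population`, `n_samples`, `he`, `pn`, `f_mean`,
#'   `ar`, `par`, sorted by decreasing `he`.
#' @export
diversity_report <- function(g, labels, g_copies = NULL) {
  labels <- check_labels(g, labels)
  rich <- allelic_richness(g, labels, g_copies)
  out <- purrr::map_dfr(unique(labels$population), function(pop) {
    samples <- pop_samples(labels, pop)
    gd <- gene_diversity(g, samples)
    f <- vapply(samples, function(s) inbreeding_f(g, s, samples), numeric(1))
    tibble(population = pop,
           n_samples = length(samples),
           he = gd$he, pn = gd$pn,
           f_mean = mean(f, na.rm = TRUE))
  })
  out <- dplyr::left_join(out, rich[, c("population", "ar", "par")],
                          by = "population")
  out <- out[order(-out$he), ]
  structure(out, g_copies = attr(rich, "g_copies"))
}
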