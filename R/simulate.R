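#' Simulate genotypes under the Balding-Nichols drift model
#'
#' Generates K populations diverged from a common ancestor. Per SNP `l` an
#' ancestral frequency `p_l` is drawn uniformly from `ancestral_maf_range`;
#' population `j` then draws its own frequency
#' `p_jl ~ Beta(p_l (1 - c_j) / c_j, (1 - p_l)(1 - c_j) / c_j)`,
#' so that `E[p_jl] = p_l` and `Var(p_jl) = c_j p_l (1 - p_l)`. The drift
#' parameter `c_j` equals the expected pairwise F_ST between two populations
#' that share it; `c_j = 0` gives `p_jl = p_l` exactly. Genotypes are
#' independent `Binomial(2, p_jl)` draws per sample (no background linkage
#' disequilibrium), and missingness, when requested, is i.i.d. across calls.
#'
#' @param n_pops Number of populations.
#' @param drift Per-population drift parameter(s) `c` in `[0, 1)`; recycled
#'   to `n_pops`.
#' @param n_snps Total number of SNPs.
#' @param samples_per_pop Diploid sample sizes; recycled to `n_pops`.
#' @param ancestral_maf_range Range `(lo, hi]` in `(0, 0.5]` for the
#'   ancestral frequency draw. SNP arrays are ascertained against rare
#'   variants, hence the default floor of 0.05.
#' @param chromosomes Either `NULL` (SNPs spread as evenly as possible over
#'   the 26 sheep autosomes plus X) or a two-column data frame
#'   (`chromosome`, `n_snps`) whose counts sum to `n_snps`.
#' @param spacing_bp Distance between adjacent simulated SNPs on a
#'   chromosome; positions sit on a regular grid since only chromosome
#'   membership feeds downstream statistics.
#' @param missing_rate Probability that any one genotype call is missing.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return A list: `genotypes` (a [geno_matrix()]), `labels` (a
#'   [pop_labels()] tibble, populations named `P1..PK`), and `truth` with
#'   `ancestral` (tibble `snp_id`, `p_anc`) and `pop_freq` (tibble
#'   `snp_id`, `population`, `p`).
#' @export
simulate_balding_nichols <- function(n_pops = 2,
                                     drift = 0.062,
                                     n_snps = 1000,
                                     samples_per_pop = 50,
                                     ancestral_maf_range = c(0.05, 0.5),
                                     chromosomes = NULL,
                                     spacing_bp = 50000L,
                                     missing_rate = 0,
                                     seed = NULL) {
  stopifnot(n_pops >= 1, n_snps >= 1,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1)
  drift <- rep_len(drift, n_pops)
  if (any(drift < 0) || any(drift >= 1)) {
    abort("drift parameters c must lie in [0, 1); c = 1 leaves the Beta undefined")
  }
  samples_per_pop <- rep_len(as.integer(samples_per_pop), n_pops)
  if (!is.null(seed)) set.seed(seed)

  if (is.null(chromosomes)) {
    chroms <- chrom_levels()
    base <- n_snps %/% length(chroms)
    extra <- n_snps %% length(chroms)
    counts <- rep(base, length(chroms)) + c(rep(1, extra),
                                            rep(0, length(chroms) - extra))
    chromosomes <- data.frame(chromosome = chroms, n_snps = counts)
  }
  chromosomes <- chromosomes[chromosomes$n_snps > 0, , drop = FALSE]
  if (sum(chromosomes$n_snps) != n_snps) {
    abort("per-chromosome SNP counts must sum to n_snps")
  }

  chrom <- rep(as.character(chromosomes$chromosome), chromosomes$n_snps)
  pos <- unlist(lapply(chromosomes$n_snps, function(k) seq_len(k) * spacing_bp))
  snp_id <- sprintf("SNP_%s_%d", chrom, pos)
  map <- snp_map(snp_id, chrom, pos, "A", "G")
  ord <- map$snp_id            # map is sorted; simulate in map order
  stopifnot(identical(sort(ord), sort(snp_id)))

  p_anc <- runif(n_snps, ancestral_maf_range[1], ancestral_maf_range[2])
  names(p_anc) <- map$snp_id

  pops <- paste0("P", seq_len(n_pops))
  pop_p <- matrix(NA_real_, n_snps, n_pops, dimnames = list(map$snp_id, pops))
  for (j in seq_len(n_pops)) {
    cj <- drift[j]
    if (cj == 0) {
      pop_p[, j] <- p_anc
    } else {
      k <- (1 - cj) / cj
      pop_p[, j] <- rbeta(n_snps, p_anc * k, (1 - p_anc) * k)
    }
  }

  n_total <- sum(samples_per_pop)
  codes <- matrix(NA_integer_, n_total, n_snps,
                  dimnames = list(NULL, map$snp_id))
  ids <- character(n_total)
  pop_of <- character(n_total)
  row <- 0L
  for (j in seq_len(n_pops)) {
    for (s in seq_len(samples_per_pop[j])) {
      row <- row + 1L
      ids[row] <- sprintf("%s_%03d", pops[j], s)
      pop_of[row] <- pops[j]
      codes[row, ] <- rbinom(n_snps, 2L, pop_p[, j])
    }
  }
  rownames(codes) <- ids
  if (missing_rate > 0) {
    drop <- matrix(runif(length(codes)) < missing_rate, nrow(codes))
    codes[drop] <- NA_integer_
  }

  truth <- list(
    ancestral = tibble(snp_id = map$snp_id, p_anc = unname(p_anc)),
    pop_freq = tibble(
      snp_id = rep(map$snp_id, n_pops),
      population = rep(pops, each = n_snps),
      p = as.vector(pop_p)
    ),
    haplotypes = NULL
  )
  list(genotypes = geno_matrix(codes, map),
       labels = pop_labels(ids, pop_of),
       truth = truth)
}

#' Define a selected haplotype block
#'
#' Describes a short window of SNPs (at most 8, on one chromosome) whose
#' genotypes are to be overwritten with draws from per-population haplotype
#' frequency vectors, emulating a locus under population-specific selection
#' such as the sheep Poll locus.
#'
#' @param window_snps SNP ids of the window, in map order.
#' @param freqs Named list: population -> named numeric vector of haplotype
#'   frequencies. Haplotype names are allele strings over the window (e.g.
#'   `"GGAA"`), each summing to 1 within 1e-9. Use
#'   [expand_haplotype_freqs()] to spread an "other" mass uniformly.
#' @param alleles Optional data frame (`snp_id`, `allele_a`, `allele_b`)
#'   overriding the window SNPs' alleles so named haplotypes such as GGAA
#'   are expressible.
#' @return A `haplotype_block` list.
#' @export
haplotype_block <- function(window_snps, freqs, alleles = NULL) {
  window_snps <- as.character(window_snps)
  if (anyDuplicated(window_snps)) abort("window SNPs must be distinct")
  m <- length(window_snps)
  for (pop in names(freqs)) {
    f <- freqs[[pop]]
    if (abs(sum(f) - 1) > 1e-9) {
      abort(sprintf("haplotype frequencies for %s sum to %.10f, not 1",
                    pop, sum(f)))
    }
    if (any(nchar(names(f)) != m)) {
      abort("haplotype names must have one allele per window SNP")
    }
  }
  structure(list(window = window_snps, freqs = freqs, alleles = alleles),
            class = "haplotype_block")
}

#' Spread residual haplotype mass uniformly
#'
#' Completes a partial haplotype frequency vector by splitting an `other`
#' mass uniformly over every haplotype of the window not explicitly named.
#'
#' @param named Named numeric vector of haplotype frequencies (allele
#'   strings as names).
#' @param other Residual mass; `sum(named) + other` must be 1.
#' @param alphabet List of per-SNP allele pairs, e.g.
#'   `list(c("A","G"), c("A","G"), ...)`, defining the haplotype space.
#' @return A full named frequency vector over all haplotypes of the window.
#' @export
expand_haplotype_freqs <- function(named, other, alphabet) {
  stopifnot(abs(sum(named) + other - 1) < 1e-9)
  all_haps <- apply(expand.grid(rev(alphabet), stringsAsFactors = FALSE),
                    1, function(x) paste(rev(x), collapse = ""))
  rest <- setdiff(all_haps, names(named))
  out <- setNames(rep(0, length(all_haps)), all_haps)
  out[names(named)] <- named
  if (length(rest) > 0) out[rest] <- other / length(rest)
  out
}

#' Inject a selected haplotype block into simulated genotypes
#'
#' For every sample, two haplotypes are drawn i.i.d. from its population's
#' frequency vector (random union of gametes) and the window's genotype
#' columns are overwritten with the implied allele-count codes. The drawn
#' pair per sample is recorded in the truth object.
#'
#' @param g A `geno_matrix`.
#' @param labels A [pop_labels()] tibble covering every sample to rewrite.
#' @param truth Truth list from [simulate_balding_nichols()] (may be NULL).
#' @param block A [haplotype_block()]; every population in `labels` must
#'   have a frequency vector.
#' @param seed Integer seed.
#' @return A list `genotypes`, `truth` where `truth$haplotypes` is a tibble
#'   (`sample_id`, `hap1`, `hap2`).
#' @export
inject_haplotype_block <- function(g, labels, truth = NULL, block, seed = NULL) {
  stopifnot(inherits(g, "geno_matrix"), inherits(block, "haplotype_block"))
  labels <- check_labels(g, labels)
  w <- block$window
  missing_snps <- setdiff(w, g$map$snp_id)
  if (length(missing_snps) > 0) {
    abort(paste0("window SNPs absent from map: ",
                 paste(missing_snps, collapse = ", ")))
  }
  chrom <- unique(g$map$chromosome[match(w, g$map$snp_id)])
  if (length(chrom) != 1) abort("window SNPs must lie on one chromosome")
  if (!is.null(block$alleles)) {
    idx <- match(block$alleles$snp_id, g$map$snp_id)
    g$map$allele_a[idx] <- block$alleles$allele_a
    g$map$allele_b[idx] <- block$alleles$allele_b
    g <- geno_matrix(g$codes, g$map)
  }
  if (!is.null(seed)) set.seed(seed)

  allele_b <- g$map$allele_b[match(w, g$map$snp_id)]
  hap_codes <- function(h) {
    as.integer(strsplit(h, "")[[1]] == allele_b)
  }
  haps <- tibble(sample_id = character(0), hap1 = character(0),
                 hap2 = character(0))
  for (pop in unique(labels$population)) {
    f <- block$freqs[[pop]]
    if (is.null(f)) {
      abort(sprintf("no haplotype frequencies supplied for population %s", pop))
    }
    samples <- pop_samples(labels, pop)
    draw <- matrix(sample(names(f), 2 * length(samples), replace = TRUE,
                          prob = f), ncol = 2)
    for (i in seq_along(samples)) {
      code <- hap_codes(draw[i, 1]) + hap_codes(draw[i, 2])
      g$codes[samples[i], w] <- code
    }
    haps <- dplyr::bind_rows(haps, tibble(sample_id = samples,
                                          hap1 = draw[, 1], hap2 = draw[, 2]))
  }
  if (is.null(truth)) truth <- list()
  truth$haplotypes <- haps
  list(genotypes = g, truth = truth)
}
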