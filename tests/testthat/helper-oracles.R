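# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive quantities with naive per-locus
# loops, never through the package's vectorised paths.

# geno_matrix from a plain codes matrix; SNPs placed on chromosome 1 (or
# as given), A/G alleles.
make_geno <- function(codes, chrom = NULL) {
  codes <- as.matrix(codes)
  n_snps <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("1", n_snps)
  map <- snp_map(paste0("snp", seq_len(n_snps)), chrom,
                 seq_len(n_snps) * 1000L, "A", "G")
  if (is.null(rownames(codes))) {
    rownames(codes) <- paste0("s", seq_len(nrow(codes)))
  }
  colnames(codes) <- paste0("snp", seq_len(n_snps))
  geno_matrix(codes, map)
}

two_pop_labels <- function(g, n1) {
  ids <- sample_ids(g)
  pop_labels(ids, c(rep("A", n1), rep("B", length(ids) - n1)))
}

# per-locus IBS loop
brute_ibs <- function(xi, xj) {
  counts <- c(ibs0 = 0L, ibs1 = 0L, ibs2 = 0L, n = 0L)
  for (l in seq_along(xi)) {
    if (is.na(xi[l]) || is.na(xj[l])) next
    counts["n"] <- counts["n"] + 1L
    d <- abs(xi[l] - xj[l])
    key <- paste0("ibs", 2L - d)
    counts[key] <- counts[key] + 1L
  }
  counts
}

# per-locus Hudson components from raw codes
brute_fst_components <- function(g, labels, pair) {
  s1 <- labels$sample_id[labels$population == pair[1]]
  s2 <- labels$sample_id[labels$population == pair[2]]
  nums <- dens <- numeric(0)
  ids <- character(0)
  for (snp in g$map$snp_id) {
    x1 <- g$codes[s1, snp]
    x2 <- g$codes[s2, snp]
    n1 <- 2 * sum(!is.na(x1)); n2 <- 2 * sum(!is.na(x2))
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(x1, na.rm = TRUE) / n1
    p2 <- sum(x2, na.rm = TRUE) / n2
    nums <- c(nums, (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
                      p2 * (1 - p2) / (n2 - 1))
    dens <- c(dens, p1 * (1 - p2) + p2 * (1 - p1))
    ids <- c(ids, snp)
  }
  list(snp_id = ids, num = nums, den = dens)
}

# Monte-Carlo rarefaction: expected distinct alleles in g copies drawn
# without replacement from (n_a, n_b) allele copies, and private variant.
mc_richness <- function(n_a, n_b, g, n_draws = 10000) {
  pool <- c(rep(0L, n_a), rep(1L, n_b))
  mean(replicate(n_draws, length(unique(sample(pool, g)))))
}

# rebuild an hclust object from a cluster_order so stats::cutree applies
as_hclust <- function(ord) {
  structure(list(merge = ord$merge, height = ord$height,
                 order = ord$order, labels = ord$labels,
                 method = "average"),
            class = "hclust")
}

# exhaustive log-likelihood oracle for the 2-SNP EM instance: one
# individual homozygous b/b at both SNPs, one double heterozygote.
# Parameterised over f11 = t, f00 = u, f01 = f10 = (1 - t - u)/2.
grid_oracle_2snp <- function(step = 0.001) {
  t <- seq(step, 1 - step, by = step)
  best <- c(ll = -Inf, t = NA, u = NA)
  for (u in seq(0, 1, by = step)) {
    tt <- t[t + u <= 1]
    if (length(tt) == 0) next
    rest <- (1 - tt - u) / 2
    ll <- 2 * log(tt) + log(2 * tt * u + 2 * rest^2)
    i <- which.max(ll)
    if (length(i) == 1 && ll[i] > best["ll"]) {
      best <- c(ll = ll[i], t = tt[i], u = u)
    }
  }
  best
}
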