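#' Per-SNP F_ST components for a population pair
#'
#' Hudson-form moment estimator. With sample allele frequencies `p1, p2`
#' and called chromosome counts `n1, n2` at SNP `l`:
#' numerator `N_l = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `D_l = p1(1-p2) + p2(1-p1)`. The ratio of sums over loci
#' (see [global_fst()]) is an unbiased estimator of the drift parameter
#' `c` of the Balding-Nichols model: for two populations with drift
#' `c1, c2` from a common ancestor its expectation is `(c1 + c2)/2`.
#' Per-SNP ratios may be negative; they are deliberately not clamped so
#' the lower tail of an outlier ranking is undistorted.
#'
#' @param g A `geno_matrix`.
#' @param labels A [pop_labels()] tibble.
#' @param pair Character vector of the two population codes.
#' @return A tibble of class `fst_components`: one row per SNP with both
#'   populations called at >= 2 chromosomes, columns `snp_id`, `p1`, `p2`,
#'   `n1`, `n2` (chromosome counts), `num`, `den`, `fst` (NA when
#'   uninformative) and `informative` (FALSE when `den = 0`, i.e. the SNP
#'   is monomorphic across both populations). The pair is kept as an
#'   attribute.
#' @export
fst_components <- function(g, labels, pair) {
  stopifnot(inherits(g, "geno_matrix"), length(pair) == 2)
  labels <- check_labels(g, labels)
  s1 <- pop_samples(labels, pair[1])
  s2 <- pop_samples(labels, pair[2])
  if (length(s1) < 2 || length(s2) < 2) {
    abort(sprintf("both populations need >= 2 samples (%s: %d, %s: %d)",
                  pair[1], length(s1), pair[2], length(s2)))
  }
  x1 <- g$codes[s1, , drop = FALSE]
  x2 <- g$codes[s2, , drop = FALSE]
  n1 <- 2 * colSums(!is.na(x1))
  n2 <- 2 * colSums(!is.na(x2))
  p1 <- colSums(x1, na.rm = TRUE) / n1
  p2 <- colSums(x2, na.rm = TRUE) / n2
  keep <- n1 >= 2 & n2 >= 2
  if (!any(keep)) {
    abort("no SNP has >= 2 called chromosomes in both populations")
  }
  snp_id <- g$map$snp_id[keep]
  p1 <- p1[keep]; p2 <- p2[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  informative <- den > 0
  out <- tibble(snp_id = snp_id, p1 = unname(p1), p2 = unname(p2),
                n1 = as.integer(unname(n1)), n2 = as.integer(unname(n2)),
                num = unname(num), den = unname(den),
                fst = unname(ifelse(informative, num / den, NA_real_)),
                informative = unname(informative))
  structure(out, class = c("fst_components", class(out)),
            pair = as.character(pair))
}

#' Global F_ST as a ratio of sums
#'
#' `sum(N_l) / sum(D_l)` over informative SNPs -- the ratio-of-sums
#' ("ratio of averages") combination, which is consistent where the mean
#' of per-SNP ratios is not. Slightly negative values are possible for
#' effectively identical populations.
#'
#' @param comp An `fst_components` tibble.
#' @return A single number.
#' @export
global_fst <- function(comp) {
  inf <- comp$informative
  if (!any(inf)) abort("no informative SNPs: F_ST undefined")
  sum(comp$num[inf]) / sum(comp$den[inf])
}

#' Bootstrap standard deviation of global F_ST
#'
#' Resamples SNP loci with replacement `n_boot` times and returns the
#' standard deviation of the ratio-of-sums F_ST across resamples. This is
#' the uncertainty from the finite marker panel.
#'
#' @param comp An `fst_components` tibble.
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param seed Integer seed.
#' @return A single non-negative number.
#' @export
bootstrap_sd <- function(comp, n_boot = 1000, seed = NULL) {
  stopifnot(n_boot >= 2)
  if (!is.null(seed)) set.seed(seed)
  num <- comp$num[comp$informative]
  den <- comp$den[comp$informative]
  l <- length(num)
  if (l == 0) abort("no informative SNPs")
  stats <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(l, l, replace = TRUE)
    sum(num[idx]) / sum(den[idx])
  }, numeric(1))
  sd(stats)
}

#' All pairwise F_ST values with bootstrap SDs
#'
#' @param g A `geno_matrix`.
#' @param labels A [pop_labels()] tibble; populations with fewer than 2
#'   samples are skipped with a warning.
#' @param n_boot Bootstrap resamples per pair.
#' @param seed Integer seed (advanced deterministically per pair).
#' @return A tibble of class `fst_pairs`: `pop1`, `pop2`, `fst`, `sd`,
#'   `n_snps` (informative loci) for every unordered pair.
#' @export
pairwise_fst_matrix <- function(g, labels, n_boot = 1000, seed = NULL) {
  labels <- check_labels(g, labels)
  pops <- unique(labels$population)
  sizes <- table(labels$population)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("skipping populations with < 2 samples: ",
                paste(small, collapse = ", ")))
    pops <- setdiff(pops, small)
  }
  if (length(pops) < 2) abort("need >= 2 populations with >= 2 samples")
  combos <- utils::combn(pops, 2)
  res <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    pair <- combos[, k]
    comp <- fst_components(g, labels, pair)
    tibble(pop1 = pair[1], pop2 = pair[2],
           fst = global_fst(comp),
           sd = bootstrap_sd(comp, n_boot,
                             seed = if (is.null(seed)) NULL else seed + k),
           n_snps = sum(comp$informative))
  })
  structure(res, class = c("fst_pairs", class(res)))
}

#' Render pairwise F_ST in reference-table layout
#'
#' Square matrix with F_ST as a percentage above the diagonal and the
#' bootstrap SD times 1000 below, zeros on the diagonal -- the layout used
#' for published between-breed divergence tables.
#'
#' @param pairs An `fst_pairs` tibble.
#' @param digits Decimals for display.
#' @return A numeric matrix with population dimnames.
#' @export
render_fst_table <- function(pairs, digits = 1) {
  pops <- unique(c(pairs$pop1, pairs$pop2))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs$pop1[r], pops)
    j <- match(pairs$pop2[r], pops)
    lo <- min(i, j); hi <- max(i, j)
    m[lo, hi] <- round_half_up(100 * pairs$fst[r], digits)
    m[hi, lo] <- round_half_up(1000 * pairs$sd[r], digits)
  }
  m
}

#' Select the top fraction of SNPs by F_ST
#'
#' SNPs are sorted by per-SNP F_ST descending (ties broken by snp_id) and
#' the smallest count covering at least fraction `q` of all ranked SNPs is
#' returned (ceiling rule: 1\% of 49,034 SNPs is 491).
#'
#' @param comp An `fst_components` tibble, or any data frame with columns
#'   `snp_id` and `fst`.
#' @param q Fraction in `(0, 1)`.
#' @return Character vector of selected snp_ids, in rank order.
#' @export
rank_top_fraction <- function(comp, q) {
  stopifnot(q > 0, q < 1)
  ranked <- comp[!is.na(comp$fst), c("snp_id", "fst")]
  ord <- order(-ranked$fst, ranked$snp_id)
  n_top <- ceiling(q * nrow(ranked))
  ranked$snp_id[ord][seq_len(n_top)]
}

#' Chromosomal enrichment of outlier SNPs
#'
#' Compares each chromosome's share of a top-F_ST SNP set against its
#' share of the whole panel. The p-value is the hypergeometric upper tail
#' P(X >= observed) for drawing `|top|` SNPs from the panel.
#'
#' @param top Character vector of top snp_ids (subset of the map).
#' @param map A SNP map tibble.
#' @return A tibble of class `enrichment_table`: per chromosome `n_snps`,
#'   `n_top`, `expected_fraction`, `observed_fraction`, `ratio`,
#'   `p_value`.
#' @export
chromosome_enrichment <- function(top, map) {
  map <- validate_snp_map(map)
  if (!all(top %in% map$snp_id)) abort("top SNPs must all be in the map")
  total <- nrow(map)
  n_top_all <- length(top)
  top_chrom <- map$chromosome[match(top, map$snp_id)]
  chroms <- unique(map$chromosome)
  chroms <- chroms[order(chrom_order(chroms))]
  out <- purrr::map_dfr(chroms, function(ch) {
    n_ch <- sum(map$chromosome == ch)
    k_ch <- sum(top_chrom == ch)
    tibble(chromosome = ch,
           n_snps = n_ch,
           n_top = k_ch,
           expected_fraction = n_ch / total,
           observed_fraction = k_ch / n_top_all,
           ratio = (k_ch / n_top_all) / (n_ch / total),
           p_value = phyper(k_ch - 1, n_ch, total - n_ch, n_top_all,
                            lower.tail = FALSE))
  })
  structure(out, class = c("enrichment_table", class(out)))
}

#' Bar chart of chromosomal enrichment
#'
#' Observed versus expected share of outlier SNPs per chromosome.
#'
#' @param object An `enrichment_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_table <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("chromosome", "expected_fraction",
                          "observed_fraction")],
    cols = c("expected_fraction", "observed_fraction"),
    names_to = "which", values_to = "fraction")
  df$which <- sub("_fraction", "", df$which)
  df$chromosome <- factor(df$chromosome, levels = chrom_levels())
  ggplot2::ggplot(df, ggplot2::aes(.data$chromosome, .data$fraction,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "chromosome", y = "fraction of SNPs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' One-row summary of an F_ST component table
#' @param x An `fst_components` tibble.
#' @param ... Unused.
#' @return A tibble with the pair, global F_ST, and locus counts.
#' @export
glance.fst_components <- function(x, ...) {
  pair <- attr(x, "pair")
  tibble(pop1 = pair[1], pop2 = pair[2],
         global_fst = global_fst(x),
         n_snps = nrow(x),
         n_informative = sum(x$informative))
}
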