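#' Identity-by-state counts for one sample pair
#'
#' Counts, over SNPs where both samples are called, the loci at which the
#' two diploid genotypes share 2, 1 or 0 alleles. With allele-count codes
#' the IBS state is `2 - |code_i - code_j|` clipped at 0 -- except that two
#' opposite homozygotes (codes 0 vs 2) share 0 alleles while a homozygote
#' and a heterozygote share 1.
#'
#' @param g A `geno_matrix`.
#' @param i,j Sample ids.
#' @return A named integer vector `c(ibs0, ibs1, ibs2, n)` with
#'   `ibs0 + ibs1 + ibs2 = n`.
#' @export
pairwise_ibs <- function(g, i, j) {
  stopifnot(inherits(g, "geno_matrix"))
  xi <- g$codes[i, ]
  xj <- g$codes[j, ]
  ok <- !is.na(xi) & !is.na(xj)
  d <- abs(xi[ok] - xj[ok])
  c(ibs0 = sum(d == 2L), ibs1 = sum(d == 1L), ibs2 = sum(d == 0L),
    n = sum(ok))
}

#' Pairwise allele-sharing matrix
#'
#' The proportion of alleles shared between two animals,
#' `A_s = (IBS2 + 0.5 IBS1) / N`, computed over the `N` SNPs at which both
#' are called (pairwise-complete). `A_s` is a similarity in `[0, 1]`; within
#' a drifting population it exceeds the between-population value, which is
#' what the ordered heatmap visualises. Computed with indicator-matrix
#' products so dense panels stay fast.
#'
#' @param g A `geno_matrix` with at least two samples.
#' @return A `sharing_matrix`: list with `values` (symmetric matrix,
#'   diagonal 1), `n` (jointly-called SNP counts per pair) and `samples`.
#' @export
sharing_matrix <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  x <- g$codes
  if (nrow(x) < 2) abort("need at least 2 samples")
  a0 <- (!is.na(x) & x == 0L) * 1
  a1 <- (!is.na(x) & x == 1L) * 1
  a2 <- (!is.na(x) & x == 2L) * 1
  called <- a0 + a1 + a2
  n <- called %*% t(called)
  mis2 <- a0 %*% t(a2) + a2 %*% t(a0)               # opposite homozygotes
  mis1 <- a1 %*% t(a0 + a2) + (a0 + a2) %*% t(a1)   # hom vs het
  if (any(n[upper.tri(n)] == 0)) {
    idx <- which(upper.tri(n) & n == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("samples %s and %s share no jointly-called SNPs",
                  rownames(x)[idx[1]], rownames(x)[idx[2]]))
  }
  values <- 1 - (0.5 * mis1 + mis2) / n
  diag(values) <- 1
  dimnames(values) <- dimnames(n) <- list(rownames(x), rownames(x))
  structure(list(values = values, n = n, samples = rownames(x)),
            class = "sharing_matrix")
}

#' @export
print.sharing_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<sharing_matrix> %d samples; off-diagonal A_s in [%.3f, %.3f]\n",
              length(x$samples), min(off), max(off)))
  invisible(x)
}

#' Tidy a sharing matrix into long form
#'
#' @param x A `sharing_matrix`.
#' @param ... Unused.
#' @return A tibble `sample_1`, `sample_2`, `a_s`, `n` over unordered pairs.
#' @export
tidy.sharing_matrix <- function(x, ...) {
  ut <- upper.tri(x$values)
  idx <- which(ut, arr.ind = TRUE)
  tibble(sample_1 = x$samples[idx[, 1]],
         sample_2 = x$samples[idx[, 2]],
         a_s = x$values[ut],
         n = as.integer(x$n[ut]))
}

#' Write a sharing matrix as TSV
#' @param x A `sharing_matrix`.
#' @param path Output path; the header row holds the sample ids.
#' @export
write_sharing_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x$values), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Order samples by average-linkage clustering of allele sharing
#'
#' Agglomerative clustering on the distance `D = 1 - A_s` with average
#' linkage, as used to arrange the allele-sharing heatmap so that related
#' animals form contiguous blocks. Leaf order is made deterministic by
#' placing, at every merge, the subtree containing the lower original
#' sample index first.
#'
#' @param s A `sharing_matrix`.
#' @return A `cluster_order`: list with `order` (permutation of sample
#'   indices), `labels`, `merge` and `height` (hclust encoding).
#' @export
cluster_order <- function(s) {
  stopifnot(inherits(s, "sharing_matrix"))
  d <- as.dist(1 - s$values)
  hc <- hclust(d, method = "average")
  # deterministic leaf order: lower original index leads at every node
  min_leaf <- function(node) {
    if (node < 0) return(-node)
    min(min_leaf(hc$merge[node, 1]), min_leaf(hc$merge[node, 2]))
  }
  leaves <- function(node) {
    if (node < 0) return(-node)
    a <- hc$merge[node, 1]
    b <- hc$merge[node, 2]
    if (min_leaf(a) <= min_leaf(b)) c(leaves(a), leaves(b))
    else c(leaves(b), leaves(a))
  }
  ord <- leaves(nrow(hc$merge))
  structure(list(order = ord, labels = s$samples, merge = hc$merge,
                 height = hc$height),
            class = "cluster_order")
}

#' @export
print.cluster_order <- function(x, ...) {
  cat(sprintf("<cluster_order> %d samples, %d merges\n",
              length(x$order), nrow(x$merge)))
  invisible(x)
}

#' Heatmap of an allele-sharing matrix
#'
#' Samples are arranged by [cluster_order()] so related animals form
#' contiguous blocks along the diagonal.
#'
#' @param object A `sharing_matrix`.
#' @param order Optional `cluster_order`; computed when NULL.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sharing_matrix <- function(object, order = NULL, ...) {
  if (is.null(order)) order <- cluster_order(object)
  ids <- object$samples[order$order]
  long <- as_tibble(expand.grid(sample_1 = ids, sample_2 = ids,
                                stringsAsFactors = FALSE))
  long$a_s <- object$values[cbind(long$sample_1, long$sample_2)]
  long$sample_1 <- factor(long$sample_1, levels = ids)
  long$sample_2 <- factor(long$sample_2, levels = rev(ids))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_1, .data$sample_2,
                                     fill = .data$a_s)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(A[s])) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
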