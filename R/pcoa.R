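#' Principal-coordinates embedding of an allele-sharing matrix
#'
#' Classical scaling of the distance `D = 1 - A_s`: the Gram matrix
#' `G = -1/2 J D^2 J` (with `J` the centering projector) is
#' eigen-decomposed and the top-`k` eigenvectors, scaled by the square root
#' of their eigenvalues, give coordinates whose Euclidean distances
#' approximate `D`. Negative eigenvalues (non-Euclidean part of `D`) are
#' excluded from the embedding and their count is reported. Eigenvector
#' sign is arbitrary, so each axis is flipped, if needed, to make its
#' largest-magnitude loading positive.
#'
#' @param s A `sharing_matrix` (or a symmetric similarity matrix in
#'   `[0, 1]` with sample dimnames).
#' @param k Number of coordinates, `k < n_samples`.
#' @return A `pcoa_result`: list with `coordinates` (n x k, rownames =
#'   samples), `eigenvalues`, `variance_explained` (fractions of the
#'   positive spectrum) and `n_negative`.
#' @export
pcoa_from_sharing <- function(s, k = 2) {
  values <- if (inherits(s, "sharing_matrix")) s$values else as.matrix(s)
  n <- nrow(values)
  if (k >= n) abort("k must be smaller than the number of samples")
  d2 <- (1 - values)^2
  j <- diag(n) - matrix(1 / n, n, n)
  gram <- -0.5 * j %*% d2 %*% j
  gram <- (gram + t(gram)) / 2
  e <- eigen(gram, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  n_pos <- sum(pos)
  k_eff <- min(k, n_pos)
  lambda <- e$values[seq_len(k_eff)]
  vec <- e$vectors[, seq_len(k_eff), drop = FALSE]
  coords <- sweep(vec, 2, sqrt(lambda), `*`)
  # deterministic sign: largest-magnitude loading positive per axis
  for (a in seq_len(ncol(coords))) {
    top <- which.max(abs(coords[, a]))
    if (coords[top, a] < 0) coords[, a] <- -coords[, a]
  }
  if (k_eff < k) {
    coords <- cbind(coords, matrix(0, n, k - k_eff))
    lambda <- c(lambda, rep(0, k - k_eff))
  }
  rownames(coords) <- rownames(values)
  colnames(coords) <- paste0("PC", seq_len(k))
  total_pos <- sum(e$values[pos])
  structure(list(coordinates = coords,
                 eigenvalues = lambda,
                 variance_explained = if (total_pos > 0) lambda / total_pos
                                      else rep(0, k),
                 n_negative = sum(e$values < -max(abs(e$values)) * 1e-12),
                 trace = sum(diag(gram))),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d axes; var explained: %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy PCoA coordinates
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @return A tibble `sample_id`, `PC1..PCk`.
#' @export
tidy.pcoa_result <- function(x, ...) {
  dplyr::bind_cols(tibble(sample_id = rownames(x$coordinates)),
                   as_tibble(x$coordinates))
}

#' One-row summary of a PCoA embedding
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @return A tibble with sample count, axes, variance explained by the
#'   first two axes and the count of negative eigenvalues.
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble(n_samples = nrow(x$coordinates),
         k = ncol(x$coordinates),
         var_pc1 = x$variance_explained[1],
         var_pc2 = if (length(x$variance_explained) >= 2)
                     x$variance_explained[2] else NA_real_,
         n_negative_eigenvalues = x$n_negative)
}

#' Recompute sharing on a SNP subset and embed
#'
#' Re-runs [sharing_matrix()] on a subset of the panel, then
#' [pcoa_from_sharing()]. Subsetting the panel is how the contribution of
#' marker number (random subsets) versus marker information (F_ST-ranked
#' subsets) to population separation is probed.
#'
#' @param g A `geno_matrix`.
#' @param snp_subset Either a character vector of SNP ids, or a single
#'   fraction in `(0, 1)` meaning a random subset of that fraction of the
#'   panel (drawn without replacement; ceiling count).
#' @param k Number of coordinates.
#' @param seed Seed for the random draw (ignored for explicit ids).
#' @return A `pcoa_result`.
#' @export
subset_and_embed <- function(g, snp_subset, k = 2, seed = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (is.numeric(snp_subset) && length(snp_subset) == 1) {
    stopifnot(snp_subset > 0, snp_subset < 1)
    if (!is.null(seed)) set.seed(seed)
    n_take <- ceiling(snp_subset * nrow(g$map))
    snp_subset <- sample(g$map$snp_id, n_take)
  }
  if (length(snp_subset) == 0) abort("snp subset is empty")
  sub <- subset_geno(g, snps = snp_subset)
  pcoa_from_sharing(sharing_matrix(sub), k = k)
}

#' Silhouette-based separation score of an embedding
#'
#' Mean silhouette coefficient of the labelled populations over the first
#' `dims` coordinates (Euclidean distance). 1 means tight, fully separated
#' clusters; about 0 means labels are unrelated to position; singleton
#' populations contribute 0.
#'
#' @param p A `pcoa_result`.
#' @param labels A [pop_labels()] tibble covering the embedded samples.
#' @param dims Number of leading coordinates to use.
#' @return A single number in `[-1, 1]`.
#' @export
separation_score <- function(p, labels, dims = 2) {
  stopifnot(inherits(p, "pcoa_result"))
  labels <- as_tibble(labels)
  ids <- rownames(p$coordinates)
  pop <- labels$population[match(ids, labels$sample_id)]
  if (any(is.na(pop))) abort("every embedded sample needs a population label")
  if (length(unique(pop)) < 2) abort("need at least 2 labelled groups")
  dims <- min(dims, ncol(p$coordinates))
  x <- p$coordinates[, seq_len(dims), drop = FALSE]
  sil <- cluster::silhouette(as.integer(factor(pop)), dist(x))
  mean(sil[, "sil_width"])
}

#' Genotype-matrix PCA with Patterson normalisation
#'
#' Cross-check variant of the embedding: PCA of the genotype matrix itself,
#' with each SNP centred at `2 p` and scaled by `sqrt(p (1 - p))`, the
#' normalisation standard for SNP PCA. Missing calls are mean-imputed for
#' the decomposition. Agrees with [pcoa_from_sharing()] on cluster topology
#' for drifted-population data.
#'
#' @param g A `geno_matrix`.
#' @param k Number of axes.
#' @return A `pcoa_result` (same shape as the sharing-based embedding).
#' @export
genotype_pca <- function(g, k = 2) {
  stopifnot(inherits(g, "geno_matrix"))
  p <- allele_freq(g)
  keep <- !is.na(p) & p > 0 & p < 1
  x <- g$codes[, keep, drop = FALSE]
  p <- p[keep]
  xs <- sweep(x, 2, 2 * p)
  xs[is.na(xs)] <- 0
  xs <- sweep(xs, 2, sqrt(p * (1 - p)), `/`)
  sv <- svd(xs, nu = k, nv = 0)
  coords <- sweep(sv$u, 2, sv$d[seq_len(k)], `*`)
  for (a in seq_len(ncol(coords))) {
    top <- which.max(abs(coords[, a]))
    if (coords[top, a] < 0) coords[, a] <- -coords[, a]
  }
  rownames(coords) <- rownames(g$codes)
  colnames(coords) <- paste0("PC", seq_len(k))
  lambda <- sv$d[seq_len(k)]^2 / max(1, nrow(x) - 1)
  total <- sum(sv$d^2) / max(1, nrow(x) - 1)
  structure(list(coordinates = coords, eigenvalues = lambda,
                 variance_explained = lambda / total,
                 n_negative = 0L, trace = total),
            class = "pcoa_result")
}

#' Scatter plot of an embedding
#'
#' @param object A `pcoa_result`.
#' @param labels Optional [pop_labels()] tibble for colouring.
#' @param dims Which two axes to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoa_result <- function(object, labels = NULL, dims = c(1, 2), ...) {
  df <- tidy.pcoa_result(object)
  xcol <- paste0("PC", dims[1])
  ycol <- paste0("PC", dims[2])
  if (!is.null(labels)) {
    labels <- as_tibble(labels)
    df$population <- labels$population[match(df$sample_id, labels$sample_id)]
  } else {
    df$population <- "all"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data[[xcol]], .data[[ycol]],
                                   colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xcol,
                  100 * object$variance_explained[dims[1]]),
      y = sprintf("%s (%.1f%%)", ycol,
                  100 * object$variance_explained[dims[2]])) +
    ggplot2::theme_minimal()
}
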