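#' EM settings for haplotype frequency estimation
#'
#' @param tol Stop when the log-likelihood increment falls below this.
#' @param max_iter Iteration cap per run.
#' @param n_restarts Total initialisations: one from the product of
#'   single-SNP allele frequencies plus `n_restarts - 1` seeded random
#'   (Dirichlet) starts; the highest-likelihood run is kept.
#' @param seed Seed for the random restarts.
#' @param min_report_freq Threshold above which a haplotype counts as
#'   "observed" in reports.
#' @return A list of settings.
#' @export
em_settings <- function(tol = 1e-8, max_iter = 1000, n_restarts = 10,
                        seed = 1, min_report_freq = 0.005) {
  stopifnot(tol > 0, n_restarts >= 1, max_iter >= 1)
  list(tol = tol, max_iter = max_iter, n_restarts = n_restarts,
       seed = seed, min_report_freq = min_report_freq)
}

# Enumerate, for a window genotype vector (codes over m SNPs, no NA), the
# compatible unordered haplotype pairs as index pairs into 0:(2^m - 1)
# (bit l set = allele_b at SNP l), with multiplicity 2 for a != b.
compatible_pairs <- function(geno) {
  m <- length(geno)
  het <- which(geno == 1L)
  base <- sum(bitwShiftL(ifelse(geno == 2L, 1L, 0L), seq_len(m) - 1L))
  h <- length(het)
  if (h == 0) {
    return(matrix(c(base, base, 1), 1, 3,
                  dimnames = list(NULL, c("a", "b", "w"))))
  }
  n_split <- bitwShiftL(1L, h - 1L)   # fix first het site on haplotype a
  out <- matrix(0L, n_split, 3, dimnames = list(NULL, c("a", "b", "w")))
  for (s in seq_len(n_split) - 1L) {
    assign_a <- c(1L, vapply(seq_len(h - 1L), function(t)
      bitwAnd(bitwShiftR(s, t - 1L), 1L), integer(1)))
    ha <- base
    hb <- base
    for (t in seq_len(h)) {
      bit <- bitwShiftL(1L, het[t] - 1L)
      if (assign_a[t] == 1L) ha <- ha + bit else hb <- hb + bit
    }
    out[s + 1L, ] <- c(ha, hb, 2L)
  }
  out
}

hap_strings <- function(map_rows) {
  m <- nrow(map_rows)
  idx <- 0:(2^m - 1)
  vapply(idx, function(h) {
    paste(vapply(seq_len(m), function(l) {
      if (bitwAnd(bitwShiftR(h, l - 1L), 1L) == 1L) map_rows$allele_b[l]
      else map_rows$allele_a[l]
    }, character(1)), collapse = "")
  }, character(1))
}

#' EM haplotype frequency estimation in a SNP window
#'
#' Excoffier-Slatkin-style expectation maximisation for multilocus
#' haplotype frequencies from unphased diploid genotypes. Each individual
#' with `H` heterozygous window sites is compatible with `2^(H-1)`
#' unordered haplotype pairs; the E-step weights pair `(a, b)`
#' proportionally to `f_a f_b` (doubled when `a != b`), and the M-step sets
#' each frequency to its expected gamete count over `2n`. Individuals with
#' any missing call in the window are excluded and counted. The
#' log-likelihood is checked to be non-decreasing at every iteration.
#'
#' @param g A `geno_matrix`.
#' @param window Character vector of SNP ids (at most 8), in map order.
#' @param samples Sample ids to use (e.g. one population); default all.
#' @param settings An [em_settings()] list.
#' @return A list: `freq` (named vector over all `2^m` haplotype allele
#'   strings), `log_likelihood`, `n_used`, `n_excluded`, `n_iter`,
#'   `converged`.
#' @export
em_haplotype_frequencies <- function(g, window, samples = NULL,
                                     settings = em_settings()) {
  stopifnot(inherits(g, "geno_matrix"))
  window <- as.character(window)
  m <- length(window)
  if (m > 8) abort("window may hold at most 8 SNPs")
  if (!all(window %in% g$map$snp_id)) abort("window SNPs must be in the map")
  if (is.null(samples)) samples <- rownames(g$codes)
  x <- g$codes[samples, window, drop = FALSE]
  complete <- rowSums(is.na(x)) == 0
  n_excluded <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x)
  if (n == 0) abort("data error: no samples with complete calls in the window")

  map_rows <- g$map[match(window, g$map$snp_id), ]
  labels <- hap_strings(map_rows)
  n_hap <- 2^m

  pair_list <- apply(x, 1, compatible_pairs, simplify = FALSE)
  pair_tab <- do.call(rbind, pair_list)
  ind_of <- rep(seq_len(n), vapply(pair_list, nrow, integer(1)))
  a_idx <- pair_tab[, "a"] + 1L
  b_idx <- pair_tab[, "b"] + 1L
  w <- pair_tab[, "w"]

  per_individual <- function(lik) {
    as.vector(rowsum(lik, ind_of))   # groups 1..n in numeric order
  }
  loglik_of <- function(f) {
    per_ind <- per_individual(w * f[a_idx] * f[b_idx])
    if (any(per_ind <= 0)) return(-Inf)
    sum(log(per_ind))
  }

  run_em <- function(f) {
    f <- f / sum(f)
    ll_old <- loglik_of(f)
    iter <- 0L
    converged <- FALSE
    while (iter < settings$max_iter) {
      iter <- iter + 1L
      lik <- w * f[a_idx] * f[b_idx]
      per_ind <- per_individual(lik)
      post <- lik / per_ind[ind_of]
      counts <- numeric(n_hap)
      # each pair contributes one copy of a and one of b per posterior unit
      inc <- rbind(cbind(a_idx, post), cbind(b_idx, post))
      agg <- rowsum(inc[, 2], inc[, 1])
      counts[as.integer(rownames(agg))] <- agg[, 1]
      f <- counts / (2 * n)
      ll <- loglik_of(f)
      if (ll < ll_old - 1e-9) {
        abort("internal error: EM log-likelihood decreased")
      }
      if (ll - ll_old < settings$tol) {
        converged <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    list(freq = f, loglik = ll_old, iter = iter, converged = converged)
  }

  # initialisation 1: product of single-SNP allele_b frequencies
  pb <- colMeans(x) / 2
  f0 <- vapply(0:(n_hap - 1), function(h) {
    prod(vapply(seq_len(m), function(l) {
      if (bitwAnd(bitwShiftR(h, l - 1L), 1L) == 1L) pb[l] else 1 - pb[l]
    }, numeric(1)))
  }, numeric(1))
  f0 <- pmax(f0, 1e-12)
  inits <- list(f0)
  if (settings$n_restarts > 1) {
    set.seed(settings$seed)
    for (r in seq_len(settings$n_restarts - 1)) {
      inits[[r + 1]] <- stats::rgamma(n_hap, 1)
    }
  }
  runs <- lapply(inits, run_em)
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  list(freq = setNames(best$freq, labels),
       log_likelihood = best$loglik,
       n_used = n, n_excluded = n_excluded,
       n_iter = best$iter, converged = best$converged)
}

#' Per-population haplotype table with named rows
#'
#' Renders per-population haplotype frequency vectors in the style of a
#' published locus table: animals used, number of haplotypes observed
#' above a frequency threshold, the named haplotypes (e.g. `H1 = GGAA`)
#' at 2 decimals, and the residual mass as `Other`.
#'
#' @param tables Named list: population -> list with `freq` (named vector
#'   over haplotype strings) and `n_used` (as returned by
#'   [em_haplotype_frequencies()]).
#' @param named Named character vector of haplotype labels to report,
#'   e.g. `c(H1 = "GGAA", H2 = "AGGT", H3 = "GGAT")`.
#' @param min_report_freq A haplotype counts as observed when its
#'   frequency exceeds this.
#' @return A tibble of class `haplotype_table`: `population`, `n_animals`,
#'   `n_haplotypes`, one column per label, `Other`.
#' @export
haplotype_report <- function(tables, named,
                             min_report_freq = 0.005) {
  if (anyDuplicated(names(named))) abort("duplicate haplotype labels")
  out <- purrr::map_dfr(names(tables), function(pop) {
    t <- tables[[pop]]
    f <- t$freq
    bad <- setdiff(unname(named), names(f))
    if (length(bad) > 0) {
      abort(paste0("named haplotypes not in the window's haplotype space: ",
                   paste(bad, collapse = ", ")))
    }
    named_f <- f[unname(named)]
    row <- tibble(population = pop,
                  n_animals = t$n_used,
                  n_haplotypes = sum(f > min_report_freq))
    for (k in seq_along(named)) {
      row[[names(named)[k]]] <- round_half_up(named_f[[k]], 2)
    }
    row$Other <- round_half_up(1 - sum(named_f), 2)
    row
  })
  structure(out, class = c("haplotype_table", class(out)))
}
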