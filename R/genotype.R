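#' Construct a genotype matrix object
#'
#' The central data container of the package: diploid biallelic SNP calls
#' coded as counts of the B allele (0, 1, 2), with `NA` for missing calls,
#' together with the marker map. Rows are samples, columns are SNPs.
#'
#' @param codes Integer matrix (samples x SNPs) with values in
#'   `{0, 1, 2, NA}`. Row names are sample ids, column names SNP ids.
#' @param map A SNP map as returned by [snp_map()]: one row per SNP with
#'   columns `snp_id`, `chromosome`, `position_bp`, `allele_a`, `allele_b`.
#' @return An object of class `geno_matrix`.
#' @seealso [read_ped_map()], [apply_qc()], [simulate_balding_nichols()]
#' @export
geno_matrix <- function(codes, map) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(rownames(codes))) {
    rownames(codes) <- paste0("S", seq_len(nrow(codes)))
  }
  map <- validate_snp_map(map)
  if (ncol(codes) != nrow(map)) {
    abort(sprintf("codes has %d SNP columns but map has %d rows",
                  ncol(codes), nrow(map)))
  }
  if (!is.null(colnames(codes))) {
    if (!setequal(colnames(codes), map$snp_id)) {
      abort("codes column names do not match map snp_ids")
    }
    codes <- codes[, map$snp_id, drop = FALSE]
  } else {
    colnames(codes) <- map$snp_id
  }
  bad <- codes[!is.na(codes) & !(codes %in% 0:2)]
  if (length(bad) > 0) {
    abort("genotype codes must be 0, 1, 2 or NA")
  }
  structure(list(codes = codes, map = map), class = "geno_matrix")
}

#' Build and validate a SNP map
#'
#' @param snp_id Character vector of unique SNP identifiers.
#' @param chromosome Chromosome labels in `1..26` or `"X"`.
#' @param position_bp 1-based physical positions.
#' @param allele_a,allele_b Allele characters in `{A, C, G, T}`;
#'   `allele_b` is the allele counted by the genotype codes.
#' @return A tibble sorted by (chromosome, position).
#' @export
snp_map <- function(snp_id, chromosome, position_bp, allele_a, allele_b) {
  m <- tibble(
    snp_id = as.character(snp_id),
    chromosome = as.character(chromosome),
    position_bp = as.integer(position_bp),
    allele_a = as.character(allele_a),
    allele_b = as.character(allele_b)
  )
  validate_snp_map(m)
}

validate_snp_map <- function(m) {
  m <- as_tibble(m)
  need <- c("snp_id", "chromosome", "position_bp", "allele_a", "allele_b")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0) {
    abort(paste0("SNP map lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(m$snp_id)) {
    abort("SNP ids must be unique")
  }
  if (!all(m$chromosome %in% chrom_levels())) {
    abort("chromosome labels must be in 1..26 or X")
  }
  if (any(m$position_bp < 1)) {
    abort("positions are 1-based and must be >= 1")
  }
  if (any(m$allele_a == m$allele_b)) {
    abort("allele_a and allele_b must differ")
  }
  m[order(chrom_order(m$chromosome), m$position_bp), ]
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d SNPs, %.1f%% missing\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Sample ids of a genotype matrix
#' @param g A `geno_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(g) rownames(g$codes)

#' Subset a genotype matrix by samples and/or SNPs
#' @param g A `geno_matrix`.
#' @param samples Sample ids to keep (default all).
#' @param snps SNP ids to keep (default all).
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(g, samples = NULL, snps = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (is.null(samples)) samples <- rownames(g$codes)
  if (is.null(snps)) snps <- g$map$snp_id
  unknown <- setdiff(snps, g$map$snp_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown snp_id: ", paste(utils::head(unknown, 5), collapse = ", ")))
  }
  unknown_s <- setdiff(samples, rownames(g$codes))
  if (length(unknown_s) > 0) {
    abort(paste0("unknown sample id: ", paste(utils::head(unknown_s, 5), collapse = ", ")))
  }
  map <- g$map[g$map$snp_id %in% snps, ]
  geno_matrix(g$codes[samples, map$snp_id, drop = FALSE], map)
}

#' B-allele frequencies
#'
#' Frequency of `allele_b` per SNP, computed over non-missing calls for an
#' optional subset of samples.
#'
#' @param g A `geno_matrix`.
#' @param samples Sample ids (default all).
#' @return Named numeric vector over SNPs (`NaN` where no calls).
#' @export
allele_freq <- function(g, samples = NULL) {
  if (is.null(samples)) samples <- rownames(g$codes)
  x <- g$codes[samples, , drop = FALSE]
  colMeans(x, na.rm = TRUE) / 2
}

# ---- PED/MAP input/output ---------------------------------------------------

#' Read genotypes from PED/MAP text files
#'
#' The MAP file carries 4 whitespace-delimited columns (chromosome, snp_id,
#' genetic distance -- ignored, position_bp). The PED file carries 6 leading
#' columns (family, sample, sire, dam, sex, phenotype) followed by one allele
#' pair per SNP; `0 0` marks a missing genotype. Alleles are assigned per SNP
#' in order of first appearance: the first allele seen becomes `allele_a`,
#' the second `allele_b` (lexicographic if both first appear in one
#' heterozygote), and codes count copies of `allele_b`. SNPs where only one
#' (or no) allele is observed get a deterministic placeholder `allele_b`
#' (`allele_a`: `A`) so the map stays well-formed.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A list with elements `genotypes` (a [geno_matrix()]) and `map`
#'   (its SNP map, sorted by chromosome and position).
#' @export
read_ped_map <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  if (any(lengths(map_fields) != 4)) {
    abort(sprintf("MAP parse error: line %d does not have 4 columns",
                  which(lengths(map_fields) != 4)[1]))
  }
  mm <- do.call(rbind, map_fields)
  n_snps <- nrow(mm)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6 + 2 * n_snps
  ragged <- which(lengths(ped_fields) != expected)
  if (length(ragged) > 0) {
    abort(sprintf(
      "PED parse error: line %d has %d fields, expected %d",
      ragged[1], lengths(ped_fields)[ragged[1]], expected))
  }
  n_samples <- length(ped_fields)
  ids <- vapply(ped_fields, `[`, character(1), 2)

  # alleles per SNP, file column-major: a1[i, l], a2[i, l]
  if (n_samples > 0) {
    pm <- do.call(rbind, ped_fields)
    a1 <- pm[, 6 + 2 * seq_len(n_snps) - 1, drop = FALSE]
    a2 <- pm[, 6 + 2 * seq_len(n_snps), drop = FALSE]
  } else {
    a1 <- a2 <- matrix(character(0), 0, n_snps)
  }

  half_missing <- (a1 == "0") != (a2 == "0")
  if (any(half_missing)) {
    idx <- which(half_missing, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "PED parse error: sample %s, SNP %s pairs allele 0 with a called allele",
      ids[idx[1]], mm[idx[2], 2]))
  }

  codes <- matrix(NA_integer_, n_samples, n_snps,
                  dimnames = list(ids, mm[, 2]))
  allele_a <- rep("A", n_snps)
  allele_b <- rep("C", n_snps)
  for (l in seq_len(n_snps)) {
    x1 <- a1[, l]
    x2 <- a2[, l]
    called <- x1 != "0"
    obs <- c(rbind(x1[called], x2[called]))   # first-seen order, pair-wise
    uniq <- unique(obs)
    if (length(uniq) > 2) {
      abort(sprintf("data error: SNP %s has >2 distinct alleles (%s)",
                    mm[l, 2], paste(uniq, collapse = ",")))
    }
    if (length(uniq) >= 1) {
      if (length(uniq) == 2) {
        # both alleles first seen in the same (heterozygous) genotype ->
        # lexicographic tie-break
        first_pair <- obs[1:2]
        if (first_pair[1] != first_pair[2]) uniq <- sort(uniq)
        allele_a[l] <- uniq[1]
        allele_b[l] <- uniq[2]
      } else {
        allele_a[l] <- uniq[1]
        allele_b[l] <- setdiff(c("A", "C", "G", "T"), uniq[1])[1]
      }
      codes[called, l] <- (x1[called] == allele_b[l]) + (x2[called] == allele_b[l])
    }
  }

  map <- snp_map(mm[, 2], mm[, 1], as.integer(mm[, 4]), allele_a, allele_b)
  g <- geno_matrix(codes[, map$snp_id, drop = FALSE], map)
  list(genotypes = g, map = g$map)
}

#' Write genotypes to PED/MAP text files
#'
#' Inverse of [read_ped_map()]: missing calls are written `0 0`, pedigree
#' columns are emitted as unknown (`sire = 0`, `dam = 0`, `sex = 0`,
#' `phenotype = -9`) and the family id equals the sample id.
#'
#' @param g A `geno_matrix`.
#' @param out_prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return Invisibly, a character vector `c(ped, map)` of the paths written.
#' @export
write_ped_map <- function(g, out_prefix) {
  stopifnot(inherits(g, "geno_matrix"))
  map_path <- paste0(out_prefix, ".map")
  ped_path <- paste0(out_prefix, ".ped")
  m <- g$map
  writeLines(sprintf("%s\t%s\t0\t%d", m$chromosome, m$snp_id, m$position_bp),
             map_path)
  n <- nrow(g$codes)
  lines <- character(n)
  for (i in seq_len(n)) {
    code <- g$codes[i, ]
    x1 <- ifelse(is.na(code), "0", ifelse(code >= 1, m$allele_b, m$allele_a))
    x2 <- ifelse(is.na(code), "0", ifelse(code == 2, m$allele_b, m$allele_a))
    lines[i] <- paste(c(rownames(g$codes)[i], rownames(g$codes)[i],
                        "0", "0", "0", "-9", c(rbind(x1, x2))),
                      collapse = "\t")
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

# ---- population labels ------------------------------------------------------

#' Read population labels
#'
#' Headerless TSV with columns sample_id, population and optionally a
#' region label (e.g. `SE`, `NE`, `CE`, `A`).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample_id`, `population` and `region`
#'   (NA when absent).
#' @export
read_pop_labels <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character")
  if (!ncol(x) %in% c(2, 3)) {
    abort("population label file must have 2 or 3 tab-separated columns")
  }
  pop_labels(x[[1]], x[[2]], if (ncol(x) == 3) x[[3]] else NA_character_)
}

#' Construct a population label table
#'
#' @param sample_id,population Character vectors of equal length.
#' @param region Optional region labels.
#' @return A tibble `sample_id`, `population`, `region`.
#' @export
pop_labels <- function(sample_id, population, region = NA_character_) {
  if (any(!nzchar(population))) abort("population codes must be non-empty")
  tibble(sample_id = as.character(sample_id),
         population = as.character(population),
         region = as.character(region))
}

check_labels <- function(g, labels) {
  labels <- as_tibble(labels)
  missing <- setdiff(labels$sample_id, rownames(g$codes))
  if (length(missing) > 0) {
    abort(paste0("labelled samples absent from genotype matrix: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  labels
}

pop_samples <- function(labels, pop) {
  labels$sample_id[labels$population == pop]
}

# ---- quality control --------------------------------------------------------

#' Generic genotype quality control
#'
#' Removes SNPs failing a call-rate or minor-allele-frequency threshold
#' (computed over all samples), then samples failing a call-rate threshold
#' over the retained SNPs. The SNP-then-sample order is fixed so that the
#' result is deterministic. A SNP fails MAF when its minor allele frequency
#' is strictly below `maf_min`, so `maf_min = 0` removes nothing and
#' `maf_min = 0.01` removes monomorphic SNPs.
#'
#' @param g A `geno_matrix`.
#' @param snp_call_rate_min,sample_call_rate_min,maf_min Thresholds in
#'   `[0, 1]`.
#' @return A list with the filtered `genotypes` and a `report` tibble with
#'   one row per filter plus totals (`n_snps_in`, `n_snps_removed`,
#'   `n_snps_out`, `n_samples_in`, `n_samples_removed`, `n_samples_out`
#'   as attributes of class `qc_report`).
#' @export
apply_qc <- function(g, snp_call_rate_min = 0, sample_call_rate_min = 0,
                     maf_min = 0) {
  stopifnot(inherits(g, "geno_matrix"),
            snp_call_rate_min >= 0, snp_call_rate_min <= 1,
            sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            maf_min >= 0, maf_min <= 1)
  called <- !is.na(g$codes)
  snp_cr <- colMeans(called)
  p <- allele_freq(g)
  maf <- pmin(p, 1 - p)
  fail_cr <- snp_cr < snp_call_rate_min
  fail_maf <- !is.na(maf) & maf < maf_min
  fail_maf[is.na(maf)] <- maf_min > 0        # no calls at all: no frequency
  keep_snps <- !(fail_cr | fail_maf)
  if (!any(keep_snps)) {
    abort("QC removed every SNP: empty panel")
  }
  g2 <- subset_geno(g, snps = g$map$snp_id[keep_snps[g$map$snp_id]])

  sample_cr <- rowMeans(!is.na(g2$codes))
  keep_samples <- sample_cr >= sample_call_rate_min
  g3 <- subset_geno(g2, samples = rownames(g2$codes)[keep_samples])

  report <- tibble(
    filter = c("snp_call_rate", "snp_maf", "sample_call_rate"),
    threshold = c(snp_call_rate_min, maf_min, sample_call_rate_min),
    n_removed = c(sum(fail_cr), sum(fail_maf), sum(!keep_samples))
  )
  report <- structure(report, class = c("qc_report", class(report)),
                      n_snps_in = ncol(g$codes),
                      n_snps_removed = sum(!keep_snps),
                      n_snps_out = ncol(g3$codes),
                      n_samples_in = nrow(g$codes),
                      n_samples_removed = sum(!keep_samples),
                      n_samples_out = nrow(g3$codes))
  list(genotypes = g3, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: SNPs %d -> %d (removed %d); samples %d -> %d (removed %d)\n",
              attr(x, "n_snps_in"), attr(x, "n_snps_out"),
              attr(x, "n_snps_removed"),
              attr(x, "n_samples_in"), attr(x, "n_samples_out"),
              attr(x, "n_samples_removed")))
  NextMethod()
}
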