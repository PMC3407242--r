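#' Load the packaged reference F_ST matrix
#'
#' A published pairwise divergence table among 14 sheep populations from
#' the ISGC SNP50 HapMap and breed diversity panel: F_ST as a percentage
#' above the diagonal, its standard deviation (x1000) below, with breed
#' codes, regions of development (SE/NE/CE Southern/Northern/Continental
#' Europe, A Asia) and animal counts. This matrix is the calibration
#' ladder against which a candidate pair's divergence is judged.
#'
#' @param path Path to a TSV in the same layout; defaults to the packaged
#'   fixture.
#' @return A list: `fst` (symmetric matrix of percentages, codes as
#'   dimnames, diagonal 0), `sd` (symmetric matrix of SD x1000) and
#'   `info` (tibble `population`, `code`, `region`, `animals`).
#' @export
read_fst_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sheep_fst_reference.tsv",
                        package = "breedline", mustWork = TRUE)
  }
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  codes <- x$code
  vals <- as.matrix(x[, codes])
  rownames(vals) <- codes
  if (any(diag(vals) != 0)) abort("fixture diagonal must be 0")
  fst <- vals
  fst[lower.tri(fst)] <- t(fst)[lower.tri(fst)]       # mirror upper triangle
  sdm <- vals
  sdm[upper.tri(sdm)] <- t(sdm)[upper.tri(sdm)]       # mirror lower triangle
  if (any(fst < 0)) abort("fixture F_ST values must be >= 0")
  list(fst = fst, sd = sdm,
       info = tibble(population = x$population, code = codes,
                     region = x$region, animals = as.integer(x$animals)))
}

#' Define a comparison category
#'
#' @param name Category name.
#' @param rule One of `"pairs"` (explicit pair list), `"all_pairs"` (every
#'   unordered pair within `populations`), `"cross"` (every pair with one
#'   member from `set1` and one from `set2`).
#' @param pairs List of 2-vectors (for `rule = "pairs"`).
#' @param populations Character vector (for `rule = "all_pairs"`).
#' @param set1,set2 Disjoint character vectors (for `rule = "cross"`).
#' @return A `category_def` list.
#' @export
category_def <- function(name, rule = c("pairs", "all_pairs", "cross"),
                         pairs = NULL, populations = NULL,
                         set1 = NULL, set2 = NULL) {
  rule <- match.arg(rule)
  if (rule == "cross" && length(intersect(set1, set2)) > 0) {
    abort("cross-category sets must be disjoint")
  }
  structure(list(name = name, rule = rule, pairs = pairs,
                 populations = populations, set1 = set1, set2 = set2),
            class = "category_def")
}

category_pairs <- function(cat) {
  switch(cat$rule,
    pairs = cat$pairs,
    all_pairs = {
      cmb <- utils::combn(cat$populations, 2)
      lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
    },
    cross = {
      unlist(lapply(cat$set1, function(a)
        lapply(cat$set2, function(b) c(a, b))), recursive = FALSE)
    })
}

#' Read category definitions from a YAML config
#'
#' @param path Path to a YAML file with a top-level `categories` list;
#'   defaults to the packaged ladder definition.
#' @return A list of [category_def()] objects.
#' @export
read_categories <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fst_categories.yaml",
                        package = "breedline", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  lapply(cfg$categories, function(c) {
    category_def(name = c$name, rule = c$rule,
                 pairs = c$pairs, populations = unlist(c$populations),
                 set1 = unlist(c$set1), set2 = unlist(c$set2))
  })
}

#' Average pairwise F_ST over a comparison category
#'
#' Unweighted mean of the category's pairwise values. The displayed value
#' is rounded half-up to 1 decimal; the unrounded mean is retained.
#'
#' @param matrix Symmetric numeric matrix of pairwise F_ST percentages
#'   with population codes as dimnames (e.g. `read_fst_fixture()$fst`).
#' @param cat A [category_def()].
#' @return A list `n`, `avg` (unrounded), `avg_display`.
#' @export
category_average <- function(matrix, cat) {
  prs <- category_pairs(cat)
  if (length(prs) == 0) abort(sprintf("category '%s' yields no pairs", cat$name))
  pops <- unique(unlist(prs))
  missing <- setdiff(pops, rownames(matrix))
  if (length(missing) > 0) {
    abort(paste0("populations absent from the matrix: ",
                 paste(missing, collapse = ", ")))
  }
  vals <- vapply(prs, function(p) matrix[p[1], p[2]], numeric(1))
  list(n = length(vals), avg = mean(vals),
       avg_display = round_half_up(mean(vals), 1))
}

#' Build the calibration table across categories
#'
#' @param matrix Symmetric F_ST percentage matrix.
#' @param cats List of [category_def()] objects (default: the packaged
#'   ladder).
#' @return A tibble of class `calibration_table`: `category`,
#'   `n_comparisons`, `avg_fst` (unrounded), `avg_fst_display`.
#' @export
calibration_table <- function(matrix, cats = read_categories()) {
  out <- purrr::map_dfr(cats, function(cat) {
    a <- category_average(matrix, cat)
    tibble(category = cat$name, n_comparisons = a$n,
           avg_fst = a$avg, avg_fst_display = a$avg_display)
  })
  structure(out, class = c("calibration_table", class(out)))
}

#' Breed-level divergence verdict for a candidate pair
#'
#' A candidate population pair is declared to show breed-level divergence
#' when its F_ST reaches or exceeds the average F_ST of the named
#' recognised-breed-pair category; the within-breed line category anchors
#' the lower end of the scale. The boundary (candidate exactly at the
#' breed average) is classified as breed-level.
#'
#' @param candidate_fst Candidate pairwise F_ST, in percent.
#' @param calib A [calibration_table()].
#' @param line_category,breed_category Names of the within-breed-lines and
#'   recognised-breed-pairs categories in `calib`.
#' @return A one-row tibble: `candidate_fst`, `line_avg`, `breed_avg`,
#'   `ratio_to_line`, `ratio_to_breed`, `verdict`, `narrative`.
#' @export
breed_verdict <- function(candidate_fst, calib,
                          line_category = "Selection lines within breed",
                          breed_category = "Breed pairs of Mediterranean origin") {
  get_avg <- function(name) {
    row <- calib[calib$category == name, ]
    if (nrow(row) != 1) abort(sprintf("category '%s' not in calibration table", name))
    row$avg_fst
  }
  line_avg <- get_avg(line_category)
  breed_avg <- get_avg(breed_category)
  breed_level <- candidate_fst >= breed_avg
  verdict <- if (breed_level) "breed-level divergence"
             else "within-breed-scale divergence"
  narrative <- sprintf(
    paste0("Candidate F_ST = %.1f%% is %.1fx the within-breed line average ",
           "(%.1f%%) and %.0f%% %s the recognised-breed-pair average (%.1f%%): %s."),
    candidate_fst, candidate_fst / line_avg, line_avg,
    abs(candidate_fst / breed_avg - 1) * 100,
    if (candidate_fst >= breed_avg) "higher than" else "lower than",
    breed_avg, verdict)
  tibble(candidate_fst = candidate_fst,
         line_avg = line_avg, breed_avg = breed_avg,
         ratio_to_line = candidate_fst / line_avg,
         ratio_to_breed = candidate_fst / breed_avg,
         verdict = verdict,
         narrative = narrative)
}
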