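#' Load the packaged Poll-locus haplotype frequency table
#'
#' Reference haplotype frequencies at the sheep Poll locus (chromosome 10)
#' for four populations, over a 4-SNP window spanning 77 kb
#' (OAR10_29469450, OAR10_29511510, OAR10_29538398, OAR10_29546872).
#' Haplotype H1 (alleles GGAA) is associated with selection for polledness;
#' H2 is AGGT and H3 is GGAT; the residual mass is `Other`.
#'
#' @return A tibble: `population`, `animals`, `haplotypes`, `H1`, `H2`,
#'   `H3`, `Other`.
#' @export
read_poll_fixture <- function() {
  path <- system.file("extdata", "poll_haplotypes.tsv",
                      package = "breedline", mustWork = TRUE)
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE,
                              stringsAsFactors = FALSE))
}

#' Canonical 4-SNP window and named haplotypes of the Poll locus
#' @return A list with `window` (the four SNP ids), `named` (labelled
#'   allele strings) and `alphabet` (per-SNP allele pairs, reference
#'   allele first).
#' @export
poll_window <- function() {
  list(window = c("OAR10_29469450", "OAR10_29511510",
                  "OAR10_29538398", "OAR10_29546872"),
       named = c(H1 = "GGAA", H2 = "AGGT", H3 = "GGAT"),
       alphabet = list(c("A", "G"), c("A", "G"), c("A", "G"), c("A", "T")))
}

#' Build a haplotype block from the Poll fixture frequencies
#'
#' Turns the fixture's named-haplotype rows into full frequency vectors
#' over the 16 window haplotypes (the `Other` mass split uniformly over
#' the unnamed ones) for injection into simulated genotypes with
#' [inject_haplotype_block()].
#'
#' @param window_snps The four SNP ids in the target map that play the
#'   role of the window (e.g. four adjacent simulated SNPs on
#'   chromosome 10).
#' @param pop_rows Named character vector: target population code ->
#'   fixture population name, e.g. `c(P1 = "Florida Native",
#'   P2 = "Louisiana Native")`.
#' @return A [haplotype_block()].
#' @export
poll_block <- function(window_snps, pop_rows) {
  fx <- read_poll_fixture()
  pw <- poll_window()
  freqs <- lapply(pop_rows, function(row_name) {
    row <- fx[fx$population == row_name, ]
    if (nrow(row) != 1) {
      abort(sprintf("population '%s' not in the Poll fixture", row_name))
    }
    named <- setNames(as.numeric(row[, c("H1", "H2", "H3")]),
                      unname(pw$named))
    expand_haplotype_freqs(named, row$Other, pw$alphabet)
  })
  names(freqs) <- names(pop_rows)
  alleles <- data.frame(
    snp_id = window_snps,
    allele_a = vapply(pw$alphabet, `[`, character(1), 1),
    allele_b = vapply(pw$alphabet, `[`, character(1), 2))
  haplotype_block(window_snps, freqs, alleles = alleles)
}
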