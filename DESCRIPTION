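Package: breedline
Title: Breed-Divergence Analysis from Dense SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether managed livestock populations are
    divergent enough to be considered separate breeds, built around dense
    SNP-array genotypes. Implements identity-by-state allele sharing with
    ordered-heatmap clustering, principal-coordinates embedding of sharing
    matrices, Hudson-form pairwise F_ST with locus-bootstrap standard
    deviations, F_ST-outlier ranking with hypergeometric chromosomal
    enrichment, EM estimation of multilocus haplotype frequencies from
    unphased genotypes, rarefaction-based allelic richness, and a
    calibration report that places a candidate pair of populations on a
    ladder of reference between-breed F_ST comparisons. A Balding-Nichols
    drift simulator generates genotypes with known structure for power and
    recovery studies, and a config-driven pipeline runs the full analysis
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
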