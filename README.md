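# breedline

Tools for a recurring question in livestock genetics: **when are two
managed lines of animals divergent enough to be called separate
breeds?** `breedline` answers it from dense SNP-array genotypes the way
population geneticists do for sheep and cattle diversity panels —
measure the candidate pair's divergence as F<sub>ST</sub> and place it on a
calibration ladder of F<sub>ST</sub> values between population pairs whose
status is already known (selection lines within a breed, recognised
breeds from the same region, different regions, different continents).

Around that inference the package provides the full supporting
workflow:

* **Genotype model** — PED/MAP text I/O, population labels, generic QC
  (call rate, MAF), missing data as a first-class sentinel.
* **Allele sharing** — pairwise identity-by-state
  A<sub>s</sub> = (IBS2 + 0.5·IBS1)/N, ordered heatmap clustering.
* **Embedding** — principal coordinates of 1 − A<sub>s</sub> (plus
  Patterson-normalised genotype PCA as a cross-check) and a silhouette
  separation score for labelled groups.
* **F<sub>ST</sub>** — Hudson-form moment estimator combined as a ratio of
  sums, unbiased for the Balding–Nichols drift parameter *c*
  (Var(p<sub>pop</sub>) = c·p(1−p); expected pairwise F<sub>ST</sub> = (c₁+c₂)/2),
  with locus-bootstrap SDs, top-fraction outlier ranking (ceiling rule)
  and hypergeometric per-chromosome enrichment.
* **Haplotype EM** — Excoffier–Slatkin-style EM for multilocus
  haplotype frequencies in short windows (e.g. the 4-SNP sheep Poll
  window), with named-haplotype report tables.
* **Diversity** — Nei-corrected gene diversity, proportion polymorphic,
  individual inbreeding F, rarefied allelic richness and private
  allelic richness.
* **Simulator** — Balding–Nichols drift simulation across 26 autosomes
  + X with optional selected-haplotype-block injection and full truth
  records, so every estimator can be tested against known parameters.
* **Pipeline** — `run_pipeline()` drives all stages from one config
  (YAML or list) with a single seed and writes every table plus a
  manifest.

Results come back as tibbles with `tidy()`/`glance()` methods and
`autoplot()` figures, so they compose with the usual dplyr/ggplot2
workflow.

## Worked example

Simulate two lines drifted from a common ancestor at c = 0.062 each
(the expected pairwise F<sub>ST</sub> is then 6.2%), estimate their
divergence, and place it on the packaged calibration ladder:

```r
library(breedline)

sim <- simulate_balding_nichols(n_pops = 2, drift = 0.062, n_snps = 5000,
                                samples_per_pop = c(40, 54), seed = 42)
comp <- fst_components(sim$genotypes, sim$labels, c("P1", "P2"))
fst  <- global_fst(comp)                     # 0.0609
bootstrap_sd(comp, n_boot = 1000, seed = 43) # 0.0014

calib <- calibration_table(read_fst_fixture()$fst)
calib
#>   category                                  n_comparisons avg_fst avg_fst_display
#> 1 Selection lines within breed                          2    1.65             1.7
#> 2 Breed pairs of Mediterranean origin                  15    4.19             4.2
#> 3 Breed pairs of Southern vs Northern Eur…              6   11.4             11.4
#> 4 Breed pairs of Asian vs European origin              14   13.6             13.6

breed_verdict(100 * fst, calib)$narrative
#> Candidate F_ST = 6.1% is 3.7x the within-breed line average (1.6%) and
#> 45% higher than the recognised-breed-pair average (4.2%):
#> breed-level divergence.
```

The estimate (6.09% ± 0.14%) recovers the simulated drift parameter
within one bootstrap SD, and the ladder reads exactly as a practitioner
would use it: the candidate pair sits above the recognised-breed rung
(4.2%) but below the between-region rung (11.4%), i.e. divergence at
the scale of separate breeds developed in the same region.

Substructure is visible without labels:

```r
s <- sharing_matrix(sim$genotypes)
p <- pcoa_from_sharing(s, k = 2)
separation_score(p, sim$labels)   # 0.78: non-overlapping clusters
autoplot(s)                       # ordered heatmap, two blocks
autoplot(p, labels = sim$labels)  # PC1 separates the lines
```

The whole analysis also runs end to end from a config:

```r
cfg <- system.file("extdata", "demo_config.yaml", package = "breedline")
manifest <- run_pipeline(cfg, output_dir = "demo_out")
```

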