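# Demonstration pipeline config: two populations drifted at c = 0.062,
# 5,000 SNPs, 40 + 54 diploids, with the Poll-locus haplotype block
# injected on chromosome 10.
seed: 1
output_dir: breedline_demo
simulation:
  n_pops: 2
  drift: [0.062, 0.062]
  n_snps: 5000
  samples_per_pop: [40, 54]
  missing_rate: 0.0
  poll_block: true
qc:
  snp_call_rate_min: 0.9
  sample_call_rate_min: 0.9
  maf_min: 0.0
fst:
  n_boot: 200
  top_fractions: [0.01, 0.05]
pca:
  k: 2
  random_fraction: 0.01
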