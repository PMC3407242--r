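# Comparison categories forming the F_ST calibration ladder among the
# 14 reference sheep populations. Rules: "pairs" lists explicit pairs,
# "all_pairs" takes every unordered pair within one set, "cross" takes
# every pair with one member from each of two disjoint sets.
categories:
  - name: "Selection lines within breed"
    rule: pairs
    pairs:
      - [MER, APM]
      - [MEL, MIL]
  - name: "Breed pairs of Mediterranean origin"
    rule: all_pairs
    populations: [MER, CAS, CHU, OJA, RAM, RAS]
  - name: "Breed pairs of Southern vs Northern European origin"
    rule: cross
    set1: [APD]
    set2: [MER, CAS, CHU, OJA, RAM, RAS]
  - name: "Breed pairs of Asian vs European origin"
    rule: cross
    set1: [SUM, TIB]
    set2: [APD, MER, CAS, CHU, OJA, RAM, RAS]
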