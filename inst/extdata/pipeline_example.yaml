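# Full-scale example configuration: seven breeding lines (six drifted
# parents of unequal size plus an admixed merged line), QC, kinship,
# core set, Fst, PCA, NJ tree, and an outlier scan of the merged line
# against its largest parent.
input:
  simulate:
    n_snps: 48000
    ancestral_maf_range: [0.01, 0.5]
    sample_missing_rate: 0
    snp_missing_rate: 0.0005
    seed: 1
    parent_lines:
      - {name: CNF, size: 46, drift_F: 0.045}
      - {name: DL,  size: 49, drift_F: 0.04}
      - {name: DN,  size: 24, drift_F: 0.12}
      - {name: FL,  size: 11, drift_F: 0.07}
      - {name: FZ,  size: 11, drift_F: 0.08}
      - {name: SB,  size: 12, drift_F: 0.06}
    admixed_line:
      name: TN
      size: 34
      dirichlet_alpha: [2.05, 1.12, 0.43, 3.50, 1.45, 1.45]
qc:
  sample_call_rate_min: 0.90
  maf_min: 0.02
  snp_call_rate_min: 1.0
tree:
  distance: fst
scan:
  pair: [CNF, TN]
  n_perm: 999
  q_threshold: 0.05
  seed: 1
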