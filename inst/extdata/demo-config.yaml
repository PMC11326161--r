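# Demo pipeline configuration: synthetic two-arm cohort with ground-truth
# intra-cage correlation 0.05, batch shifts, light censoring; all stages on.
seed: 7
generate:
  n_cages_per_arm: 150
  cluster_size: 4
  n_arms: 2
  icc: 0.05
  marginal_mean: 30
  marginal_sd: 5
  censor_rate: 0.02
  batch_labels: [g1, g2]
  batch_shifts: [1.5, -1.5]
batch_adjust:
  batch: batch
  fixed_terms: [arm]
icc:
  fixed_terms: [arm]
permutation:
  n_perm: 1000
  estimator: anova
sample_size:
  strata:
    stratum: [outbred]
    mean: [912.0]
    sd: [143.0]
  icc_list: [0.0, 0.01, 0.05, 0.1]
  k_list: [4]
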