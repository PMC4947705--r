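# Example angiotraj run configuration. Any omitted block uses package
# defaults; this file shrinks the cohort and the MCMC for a quick run.
seed: 7
biomarker: Tie2
cohort:
  n_standard: 12
  n_experimental: 12
  missing_rate: 0.0
  censor_rate: 0.0
  pfs_distribution:
    name: fixed
    days: 300
mcmc:
  n_chains: 2
  n_adapt: 300
  n_warmup: 300
  n_draws: 500
pseudo_trial:
  n_replicates: 500
  visit_interval_days: 30
  visit_jitter_days: 5
rules:
  Tie2: 0.5
  Ca125: 1.0
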