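# Default run configuration for the southwest Florida manatee analysis
# span. The survey estimates are the published lognormal approximations
# of the 2011 and 2016 detection-corrected aerial surveys; the initial
# abundance prior is the doubled-SD lognormal constructed from the
# pooled hindcast ensembles.
years: [1997, 2016]
surveys: surveys.csv
init_abundance: {mu_log: 7.38, sd_log: 0.49}
sampler:
  n_chains: 3
  n_iter: 60000
  n_burnin: 20000
  thin: 10
  seed: 1
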