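event_time_prior:
  shape: 1.0
  mean: 0.01
leaf_population_size_prior:
  shape: 5.0
  mean: 0.002
root_relative_population_size_prior:
  shape: 100.0
  mean: 1.0
freq_1: 0.5
concentration:
  fixed: 1.414216
mu: 1.0
use_constant_characters: yes
correction: per_site
mcmc:
  generations: 2000.0
  sample_every: 5.0
  chains: 2.0
  seed: 1.0
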