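L: 8
alleles_per_locus:
- 5
- 7
source_freq_model: dirichlet
alpha: 0.4
geometric_r: 0.6
clusters:
- name: north
  n_founders: 10
  drift_generations: 8
  census_size: 60
  n_sampled: 30
- name: south
  n_founders: 6
  drift_generations: 8
  census_size: 40
  n_sampled: 20
migration_rate: 0.02
admix_generations: 2
missing_rate: 0.01
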