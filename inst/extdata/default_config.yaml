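# default analysis configuration: mirrors agrimeta::default_analysis_config()
model:
  subgroup_terms: [functional_group, taxon_group, crop_type, scale]
  refs:
    scale: farm
    taxon_group: arthropods
    functional_group: producers
    crop_type: cereals
  pct_arable_as_proportion: true
  outlier_threshold: 2.0
hblm:
  phi: profile
  n_tau: 201
  tau_max: null          # default: 10 * sqrt(typical within-study variance)
  phi_grid: [0.0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5,
             0.55, 0.6, 0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95]
bias:
  trim_fill_side: right
level: 0.95
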