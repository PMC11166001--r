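# Demonstration pipeline configuration on a fully synthetic survey:
# two seasons x two lifestyles, four sites along an environmental gradient,
# selection-structured communities with two planted correlation blocks.
version: 1
synth:
  n_otus: 250
  groups:
    season: [summer, summer, winter, winter]
    lifestyle: [FL, PA, FL, PA]
    n_sites: [4, 4, 4, 4]
    n: [12, 12, 12, 12]
  library_meanlog: 8.0     # ~3000 reads
  library_sdlog: 0.25
  trait_signal: 6
  sigma_sel: 1.5
  env_range: 6
  env_mode: site_gradient
  dispersal: well_mixed
  blocks:
    - {size: 5, rho: 0.9}
    - {size: 5, rho: 0.9}
  seed: 42
rarefaction:
  depth: min
  seed: 101
assembly:
  n_null: 199
  weighted: true
  groups: [season, lifestyle]
  seed: 202
network:
  min_mean_ra: 1.0e-4
  min_prevalence: 0.20
  rho_threshold: 0.7
  q_threshold: 0.01
  split: [season, lifestyle]
  seed: 303
stats:
  mantel_vars: [temperature, salinity]
  n_perm: 999
  seed: 404
anosim:
  groups: [season, lifestyle]
  n_perm: 999
  seed: 505
out_dir: pipeline-demo-out
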