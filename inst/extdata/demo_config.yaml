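# Demo run: simulated cohort on a 2 x 20 Mb synthetic genome.
# Any key omitted here falls back to defaultRunConfig(); unknown keys are
# rejected.
out_dir: hmcfrag_demo
seed: 1
simulate:
  enabled: true
  n_cancer: 40
  n_healthy: 40
  fragments_per_sample: 20000
  short_excess_cancer: 0.1
  effect_log2fc: 2.0
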