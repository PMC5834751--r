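# Default run configuration: study-condition thresholds and simulation
# parameters. Any key omitted falls back to the package default.
seed: 1
runin_threshold: 0.5
confidence_split: 4
output_dir: "."
sim:
  n_participants: 50
  p_female: 0.56
  commit_prob: 0.96
  conf_high_prob: 0.6
  adherence_high: 0.98
  adherence_low: 0.76
  resp_thu_sun: 0.82
  resp_fri_sat: 0.58
  p_low_engager: 0.24
  low_engager_resp: 0.2
  max_blocks: 6
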