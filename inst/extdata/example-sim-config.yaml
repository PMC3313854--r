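# Example simulation configuration for `updrsalert simulate --config ...`
n_patients: 47
n_pairs: 74
n_experts: 4
expert_noise: 0.15
seed: 1
labeler:
  weights: {d13: 1, d14: 1, d29: 1}
  warn_at: 1
  alarm_at: 2
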