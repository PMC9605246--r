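# Small end-to-end demonstration: 3 synthetic participants, 5-minute
# sessions, all three learning strategies.
cohort:
  n_participants: 3
  session_minutes: 5
  atypical_fraction: 0
split:
  train_fraction: 0.8
  mode: stratified_random
strategies:
  - individual
  - centralized
  - federated
federated:
  rounds: 20
output_dir: stressfl-demo-output
seed: 7
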