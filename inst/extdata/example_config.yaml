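# Example run configuration. Every field is optional; omitted fields take the
# package defaults, which reproduce the documented screening strategy
# (52-week interval, sensitivity 0.96, specificity 0.94, outcome
# probabilities 0.04/0.93/0.03, 4-week notice, 10-minute wait, 10 cycles,
# 5 replicates, 10,000 agents).
seed: 1
output_dir: results

population:
  total_size: 10000
  frac_never_called: 0.30

screening:
  interval_weeks: 52
  sensitivity: 0.96
  specificity: 0.94
  p_positive: 0.04
  p_negative: 0.93
  p_inconclusive: 0.03
  notice_weeks: 4
  waiting_time_minutes: 10
  reminder_score: 20
  n_cycles: 10
  n_replicates: 5

decision:
  mode: logistic          # logistic | fuzzy | combined
  weight_logistic: 0.5
  weight_fuzzy: 0.5
  variability: 0
  decision_policy: bernoulli

scenarios: []
# e.g.
# scenarios:
#   - preset: positive_result
#   - name: uplift_rural
#     action: add
#     amount: 0.05
#     where:
#       - field: urbanization
#         op: "<"
#         value: 0.4
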