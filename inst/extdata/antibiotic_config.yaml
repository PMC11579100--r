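# Antibiotic dose-optimization problem: minimize drug AUC subject to the
# mean bacterial count over 6-24 h staying at or below 100.
name: antibiotic_ar
model:
  name: antibiotic_ar
records: antibiotic_doses.csv
infusion_durations: [1]     # 1 h infusion into compartment 1 (the D1 analogue)
mode: optimize_doses
time_unit: h
m: 1
bounds:
  lower: [5]
  upper: [150]
cost:
  observable: C
  window: [0, 24]
  type: integral
constraints:
  - kind: mean_value
    observable: S
    direction: upper
    threshold: 100
    window: [6, 24]
    name: S_mean
penalty:
  schedule: [100, 10000, 1000000]
optimizer:
  D_init: [80]
  seed: 1
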