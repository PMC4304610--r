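# Exposure-factor risk functions: daily e-liquid consumption (ml/day,
# normal solved from its 25th/75th percentiles), vaporized percentage (%),
# bodyweight (kg).  All truncated below at 0.
amount:
  family: normal_from_quantiles
  params: [0.25, 3, 0.75, 5]
  truncate: [0, ~]
  unit: ml/day
vaporization:
  family: uniform
  params: [6, 81]
  unit: "%"
bodyweight:
  family: normal
  params: [73.9, 12]
  truncate: [0, ~]
  unit: kg
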