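# Concentration risk functions for the seven assessed agents, in the
# package's config dialect (see as_risk_config).  Parametric parameter
# order: normal [mean, sd]; weibull_shifted [shape, scale] (+ shift);
# triangular [min, mode, max]; loglogistic [location, scale, shape].
# All are truncated below at 0.  The empirical vectors for the three
# low-incidence agents include zeros for non-detects; the 1,3-propanediol
# and ethyl vanillin positive values are synthetic reconstructions matching
# the reported summary statistics (raw data unpublished).
nicotine:
  family: normal
  params: [11.023, 13.134]
  truncate: [0, ~]
  unit: mg/ml
glycerol:
  family: weibull_shifted
  params: [1.8104, 44.812]
  shift: -2.8327
  truncate: [0, ~]
  unit: g/100g
propylene_glycol:
  family: triangular
  params: [-18.939, 91.8, 100.45]
  truncate: [0, ~]
  unit: g/100g
ethylene_glycol:
  family: loglogistic
  params: [-0.40204, 5.15, 1.8215]
  truncate: [0, ~]
  unit: g/100g
propanediol_13:
  family: empirical_resample
  params: [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
           0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
           0, 0, 0, 0, 0, 0, 0,
           3.3, 3.3, 3.5, 3.8, 4.2, 5.6, 8.7]
  unit: g/100g
thujone:
  family: empirical_resample
  params: [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
           0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
           0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
           183, 178]
  unit: mg/L
ethyl_vanillin:
  family: empirical_resample
  params: [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
           0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
           7.7, 16.8, 29.3, 43.6, 59.1, 75.6, 93, 111.1, 129.9, 149.3,
           169.2, 189.7, 210.6, 335]
  unit: mg/L
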