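# Toxicological reference points for MOE calculation, in mg/kg bw/day.
# The primary value is the most sensitive endpoint (LOAEL/NOAEL/NOEL/BMDL10);
# secondary values are health-based guidance values (ADI or MRL) kept for
# comparison statements only.
nicotine:
  endpoint: Heart rate acceleration in humans
  value: 0.008
  endpoint_type: LOAEL
  endpoint_source: human
  secondary_value: 0.0008
  secondary_type: ADI
  reference: EFSA opinion on nicotine residues, based on human i.v. dosing
glycerol:
  endpoint: 2-year dietary study in rats, no effects observed
  value: 10000
  endpoint_type: NOAEL
  endpoint_source: animal
  reference: OECD SIDS glycerol dossier
propylene_glycol:
  endpoint: 2-year studies in rats and dogs (erythrocyte destruction in dogs)
  value: 2500
  endpoint_type: NOAEL
  endpoint_source: animal
  secondary_value: 25
  secondary_type: ADI
  reference: JECFA evaluation of propylene glycol
ethylene_glycol:
  endpoint: Developmental toxicity in mice (malformations, skeletal variation)
  value: 76
  endpoint_type: BMDL10
  endpoint_source: animal
  secondary_value: 0.8
  secondary_type: MRL
  reference: ATSDR toxicological profile for ethylene glycol
propanediol_13:
  endpoint: Developmental toxicity study in rats
  value: 1000
  endpoint_type: NOAEL
  endpoint_source: animal
  reference: EFSA CONTAM panel statement on 1,3-propanediol
thujone:
  endpoint: Clonic seizures in rats
  value: 11
  endpoint_type: BMDL10
  endpoint_source: animal
  secondary_value: 0.11
  secondary_type: ADI
  reference: Benchmark-dose analysis of the NTP thujone bioassay
ethyl_vanillin:
  endpoint: 13-week dietary study in rats, no effects observed
  value: 500
  endpoint_type: NOEL
  endpoint_source: animal
  secondary_value: 3
  secondary_type: ADI
  reference: JECFA evaluation of ethyl vanillin
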