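# Default synthetic-corpus configuration: 24 interviews over 22 value
# codes and 41 biophysical element codes, heavy-tailed background
# co-occurrence, and ten planted core pairs oversampled 20x.
n_values: 22
n_biophysical: 41
n_interviews: 24
segments_per_interview:
  mean: 12
  dispersion: 5
mentions_per_segment:
  mean: 8
  dispersion: 4
background_concentration: 1.0
p_value_value: 0.55
seed: 1
planted_pairs:
  - {source: PETRELS, target: HAR, multiplier: 20}
  - {source: SEA, target: PTL, multiplier: 20}
  - {source: SEA, target: PTP, multiplier: 20}
  - {source: LANDBIRDS, target: GOV, multiplier: 20}
  - {source: SEA, target: STE, multiplier: 20}
  - {source: PRE, target: STE, multiplier: 20}
  - {source: PTP, target: PTL, multiplier: 20}
  - {source: PTL, target: PTA, multiplier: 20}
  - {source: GOV, target: STE, multiplier: 20}
  - {source: PTP, target: STE, multiplier: 20}
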