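# Example vital-rate override file: a population with higher renesting
# propensity and a slightly smaller second clutch. Parameters not listed
# keep the package defaults.
renest:
  mean: 0.45
  sd: 0.10
clutch2:
  mean: 7.5
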