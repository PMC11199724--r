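# Default anchor-keyword sets for the five grouped TRL categories.
# TRL1: basic research identifying extracts and fundamental principles.
# TRL2: isolation of substances, fractionation, chemical characterization.
# TRL3: in vitro and in silico testing.
# TRL4-5: in vivo animal testing, formulation research, patenting (grouped:
#   patent activity is rarely visible in publications on its own).
# TRL6-9: clinical trials of any phase, plus traditional-use/population
#   response studies treated as clinical evidence in the broad sense.
# Replace via the `keywords` entry of a run config; terms are matched on
# their preprocessed tokens.
TRL1:
  - extract identification
  - crude extract
  - ethnobotanical survey
  - bioprospecting
  - phytochemical screening
TRL2:
  - isolation
  - fractionation
  - chemical characterization
  - purification
  - structure elucidation
  - chromatography
TRL3:
  - in vitro
  - in silico
  - cell culture
  - molecular docking
  - cytotoxicity assay
  - ic50
TRL4_5:
  - in vivo
  - animal model
  - mice
  - rats
  - formulation
  - patent
  - preclinical toxicity
TRL6_9:
  - clinical trial
  - phase
  - tolerability
  - pharmacokinetics
  - efficacy
  - randomized placebo
  - patients
  - traditional use
  - population response
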