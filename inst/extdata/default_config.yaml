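registry:
  domain_codes:
    cardiac:
    - I42
    - I50
    - I44
    - I45
    - I46
    - I47
    - I48
    - I49
    cerebrovascular:
    - I60
    - I61
    - I62
    - I63
    - I64
    - G45
    renal: N18
  riskfactor_codes:
    diabetes:
    - E10
    - E11
    - E12
    - E13
    - E14
    dyslipidemia: E78
    hypertension:
    - I10
    - I11
    - I12
    - I13
    - I15
    obesity: E66
    smoking:
    - F17
    - Z720
  severity_weights:
  - 4.0
  - 3.0
  - 3.0
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  - 2.0
  - 4.0
  - 4.0
  - 4.0
  - 3.0
  - 3.0
  - 2.0
  - 2.0
scoring_map:
  renal_egfr:
    breaks:
    - 90.0
    - 60.0
    - 30.0
    points:
    - 0.0
    - 1.0
    - 2.0
    - 4.0
  renal_uacr:
    breaks:
    - 30.0
    - 300.0
    points:
    - 0.0
    - 1.0
    - 4.0
  cardiac_weights:
  - 1.0
  - 2.0
  - 3.0
  - 4.0
  cerebrovascular_weights:
  - 1.0
  - 2.0
  - 3.0
  - 4.0
  pain_weights:
  - 0.0
  - 1.0
  - 2.0
  - 4.0
  domain_max: 4.0
  dichotomization_threshold: 4.0
  youden_reference: 4.4
  cv_score_threshold: 1.92
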