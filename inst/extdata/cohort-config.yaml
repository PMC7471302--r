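# Example cohort-builder configuration.
#
# The code lists shipped here are synthetic placeholders matching the
# codes emitted by the bundled claims generator. For real claims,
# replace them with the validated national code lists (imaging
# procedure codes, comorbidity ICD-10 prefixes, severity-index
# predictors and their published coefficients).
imaging_codes: [HA401, HA402, HE101, HE102]
admission_window_days: 30
imaging_window_days: 30
first_stay_days: 30
min_age: 18
comorbidity_map:
  atrial_fibrillation: [I48]
  chf: [I50]
  ckd: [N18]
  copd: [J43, J44]
  diabetes: [E10, E11, E12, E13, E14]
  hyperlipidemia: [E78]
  hypertension: [I10, I11, I12, I13, I15]
  ihd: [I20, I21, I22, I23, I24, I25]
  tia: [G45]
ssi_codes:
  icu_admission: [ICUADM]
  mechanical_ventilation: [MVENT]
  nasogastric_tube: [NGTUBE]
ssi:
  intercept: 4.1
  score_min: 4.1
  score_max: 27.11
  coefficients:
    icu_admission: 3.2
    mechanical_ventilation: 4.5
    nasogastric_tube: 2.1
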