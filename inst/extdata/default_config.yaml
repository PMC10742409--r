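amplicon:
  length: 117
  cut_site1: 43
  cut_site2: 75
  measurable_min: 40
stoichiometry: calibrated
deconvolution: standard
divisors: conventional
noise_cv: 0.05
n_molecules: 10000
sampling: multinomial
cohort:
  n_t1d: 36
  n_control: 29
  n_molecules: 10000
  noise_cv: 0.05
  t1d:
    composition:
    - 0.328435
    - 0.418705
    - 0.25286
    logit_scale:
    - 0.0
    - 0.093551
    - 0.557279
    effect_hba1c_partial: 0.091899
    effect_aad_partial: -0.026613
    effect_aad_mCmC: 0.263058
  control:
    composition:
    - 0.320722
    - 0.360963
    - 0.318315
    logit_scale:
    - 0.178838
    - 0.103484
    - 0.507293
  covariates:
    t1d:
      age_at_diagnosis:
        median: 14.0
        iqr:
        - 9.5
        - 21.0
        log: no
      duration:
        median: 12.0
        iqr:
        - 4.0
        - 20.5
        log: yes
      sbp:
        median: 120.0
        iqr:
        - 110.0
        - 130.0
        log: no
      dbp:
        median: 75.0
        iqr:
        - 70.0
        - 80.0
        log: no
      bmi:
        median: 22.0
        iqr:
        - 21.0
        - 23.0
        log: no
      fasting_glucose:
        median: 116.5
        iqr:
        - 95.5
        - 170.5
        log: yes
      hba1c:
        median: 7.5
        iqr:
        - 6.8
        - 8.0
        log: no
      p_male: 0.556
    control:
      age:
        median: 29.0
        iqr:
        - 22.0
        - 33.0
        log: no
      sbp:
        median: 115.0
        iqr:
        - 100.0
        - 125.0
        log: no
      dbp:
        median: 75.0
        iqr:
        - 70.0
        - 80.0
        log: no
      bmi:
        median: 22.2
        iqr:
        - 21.0
        - 23.0
        log: no
      fasting_glucose:
        median: 82.0
        iqr:
        - 76.0
        - 90.0
        log: yes
      hba1c:
        median: 5.1
        iqr:
        - 4.8
        - 5.3
        log: no
      p_male: 0.586
  p_complications: 0.3
cutoff: 15.0
seed: 1
out_dir: '.'
log_level: info
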