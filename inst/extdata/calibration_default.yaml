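# Default calibration of the statistical-emulation cohort generator.
# Group-conditional targets for each model feature: mean/sd entries are
# matched by moment-matched truncated normals (bounds = physical
# plausibility, units mm / degrees / MPa / percent), median/q1/q3 entries by
# quantile-matched log-normal (Cpmax, positive and right-skewed) or
# logit-normal on [0, 100] (CPI, bounded percentage).
outcome_counts:
  total: 151
  ca: 89
  ppi: 32
  lbbb: 78
  rbbb: 1
features:
  ibms_length:
    family: truncnorm
    bounds: [0.5, 30]
    ca:    {mean: 10.06, sd: 3.64}
    no_ca: {mean: 10.09, sd: 2.98}
  ibms_angle:
    family: truncnorm
    bounds: [0, 90]
    ca:    {mean: 21.67, sd: 16.91}
    no_ca: {mean: 16.50, sd: 18.74}
  d3:
    family: truncnorm
    bounds: [-12, 8]
    ca:    {mean: -1.87, sd: 2.30}
    no_ca: {mean: -2.44, sd: 2.20}
  annular_diameter:
    family: truncnorm
    bounds: [16, 34]
    ca:    {mean: 24.39, sd: 2.10}
    no_ca: {mean: 23.60, sd: 1.87}
  doi:
    family: truncnorm
    bounds: [-5, 25]
    ca:    {mean: 7.30, sd: 3.91}
    no_ca: {mean: 4.79, sd: 4.02}
  sizing_index:
    family: truncnorm
    bounds: [0.85, 1.55]
    ca:    {mean: 1.12, sd: 0.09}
    no_ca: {mean: 1.15, sd: 0.10}
  cpmax:
    family: lognormal
    ca:    {median: 0.55, q1: 0.41, q3: 0.79}
    no_ca: {median: 0.30, q1: 0.06, q3: 0.56}
  cpi:
    family: logitnormal
    scale: 100
    ca:    {median: 28, q1: 18, q3: 44}
    no_ca: {median: 10, q1: 1, q3: 26}
# Device-type frequencies per outcome group (counts; CV, ER/EPRO, LT).
device_type_counts:
  levels: ["CV", "ER/EPRO", "LT"]
  ca:    [50, 9, 30]
  no_ca: [33, 15, 14]
# Device-size frequencies nested within type, per outcome group.
device_size_counts:
  levels: ["CV 26", "CV 29", "CV 31", "ER/EPRO 26", "ER/EPRO 29", "LT 23", "LT 25", "LT 27"]
  type:   ["CV", "CV", "CV", "ER/EPRO", "ER/EPRO", "LT", "LT", "LT"]
  ca:    [17, 28, 5, 2, 7, 5, 12, 13]
  no_ca: [12, 20, 1, 7, 8, 6, 6, 2]
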