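{
  "name": "normal_ci",
  "angle_mean_deg": 33.0,
  "angle_sd_deg": 6.1,
  "length_mean_mm": 31.9,
  "length_sd_mm": 2.4,
  "landmark_jitter_sd_mm": 0,
  "age_mean_yr": 63.9,
  "age_sd_yr": 21.3,
  "female_fraction": 0.4667,
  "mfp_tilt_deg": 0,
  "provenance": "Published cochlear-implant cohort with normal middle-ear function, cone-beam temporal-bone CT, 30 subjects (60 ears): mandibular-fossa-plane ET angle 33.0 (6.1) deg, length 31.9 (2.4) mm; age 63.9 (21.3) yr, 14/30 female. The cohort-comparison length figures are used where published length summaries disagree between reports of the same cohort."
}
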