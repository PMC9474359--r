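{
  "name": "cholesteatoma",
  "angle_mean_deg": 27.8,
  "angle_sd_deg": 5.1,
  "length_mean_mm": 25.9,
  "length_sd_mm": 5.1,
  "landmark_jitter_sd_mm": 0,
  "age_mean_yr": 42.5,
  "age_sd_yr": 14.3,
  "female_fraction": 0.3333,
  "mfp_tilt_deg": 0,
  "provenance": "Published acquired-cholesteatoma cohort, 30 subjects (60 ears): mandibular-fossa-plane ET angle 27.8 (5.1) deg, length 25.9 (5.1) mm; age 42.5 (14.3) yr, 10/30 female."
}
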