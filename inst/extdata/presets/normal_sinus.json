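{
  "name": "normal_sinus",
  "angle_mean_deg": 34.7,
  "angle_sd_deg": 5.2,
  "length_mean_mm": 31.3,
  "length_sd_mm": 3.7,
  "landmark_jitter_sd_mm": 0,
  "age_mean_yr": 46,
  "age_sd_yr": 13,
  "female_fraction": 0.4667,
  "mfp_tilt_deg": 1.7,
  "provenance": "Published normal-middle-ear sinus-CT cohort, 30 subjects (60 ears): mandibular-fossa-plane ET angle 34.7 (5.2) deg, length 31.3 (3.7) mm; tilt set so the Reid's-plane mean angle is 1.7 deg lower, matching the published plane offset. Age sd reconstructed from the reported range."
}
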