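#!/usr/bin/env Rscript
# Measure every ear of the simulated sinus-CT cohort against Reid's standard
# plane and against the mandibular-fossa plane, and compare the two methods.
# The mandibular fossa replaces the infraorbital margin as plane anchor; if
# the two planes were interchangeable, angle summaries should differ only by
# the small systematic plane tilt and lengths should be identical (the chord
# between the orifices does not involve the reference plane at all).

library(etmorph)

sets <- read_landmarks("results/landmarks_normal_sinus.csv")

for (plane in c("REIDS", "KC_MFP")) {
  m <- measure_cohort(sets, plane)
  write_measurements(m, sprintf("results/measurements_normal_sinus_%s.tsv",
                                tolower(plane)))
  cat(sprintf("%-7s angle %.1f (%.1f) deg   length %.1f (%.1f) mm   (n = %d ears)\n",
              plane, mean(m$angle_deg), sd(m$angle_deg),
              mean(m$length_mm), sd(m$length_mm), nrow(m)))
}

rsp <- read_measurements("results/measurements_normal_sinus_reids.tsv")
mfp <- read_measurements("results/measurements_normal_sinus_kc_mfp.tsv")
ta <- t_test_from_samples(rsp$angle_deg, mfp$angle_deg)
cat(sprintf("plane comparison, angle:  t = %.2f, p = %s (unpaired Student)\n",
            ta$statistic, format_p(ta$p)))
cat(sprintf("length is plane-independent: max |RSP - MFP| = %.2e mm\n",
            max(abs(rsp$length_mm - mfp$length_mm))))

# also the temporal-bone cone-beam cohort, measurable only with the
# mandibular-fossa plane (the orbits are outside a temporal-bone field of view)
ci <- measure_cohort(read_landmarks("results/landmarks_normal_ci.csv"), "KC_MFP")
write_measurements(ci, "results/measurements_normal_ci_kc_mfp.tsv")
ch <- measure_cohort(read_landmarks("results/landmarks_cholesteatoma.csv"), "KC_MFP")
write_measurements(ch, "results/measurements_cholesteatoma_kc_mfp.tsv")
cat(sprintf("CI cohort:  angle %.1f (%.1f) deg, length %.1f (%.1f) mm\n",
            mean(ci$angle_deg), sd(ci$angle_deg), mean(ci$length_mm), sd(ci$length_mm)))
cat(sprintf("CH cohort:  angle %.1f (%.1f) deg, length %.1f (%.1f) mm\n",
            mean(ch$angle_deg), sd(ch$angle_deg), mean(ch$length_mm), sd(ch$length_mm)))
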