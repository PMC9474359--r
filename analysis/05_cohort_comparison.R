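#!/usr/bin/env Rscript
# The clinical question: do ears with acquired cholesteatoma have more
# horizontal (smaller-angle) and shorter Eustachian tubes than ears with
# normal middle-ear function? Compares the simulated cochlear-implant and
# cholesteatoma cohorts measured with the mandibular-fossa plane, plus the
# sample-size calculation the design rests on.

library(etmorph)

n <- min_sample_size(sd = 4.8, delta = 3.9, alpha = 0.05, power = 0.8)
cat(sprintf("sample size: sd %.1f deg, detectable difference %.1f deg, 95%% confidence, 80%% power -> %d ears per group (unrounded %.1f)\n",
            n$sd, n$delta, n$n_per_group, n$n_exact))

ci <- read_measurements("results/measurements_normal_ci_kc_mfp.tsv")
ch <- read_measurements("results/measurements_cholesteatoma_kc_mfp.tsv")
report <- compare_cohorts(
  ci, ch,
  read_demographics("results/demographics_normal_ci.csv"),
  read_demographics("results/demographics_cholesteatoma.csv"),
  label_a = "cochlear implant", label_b = "cholesteatoma")
print(report)
write_report(report, "results/comparison_ci_vs_cholesteatoma.json",
             "results/comparison_ci_vs_cholesteatoma.tsv")
cat("report written to results/comparison_ci_vs_cholesteatoma.{json,tsv}\n")
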