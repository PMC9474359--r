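test_that("summary t test reproduces frozen pooled-variance cases", {
  # cohort-comparison angle summaries: t = 5.066, df = 118, p = 1.52e-6
  r <- t_test_from_summary(summary_stats(60, 33.0, 6.1), summary_stats(60, 27.8, 5.1))
  expect_equal(r$statistic, 5.065843, tolerance = 1e-6)
  expect_equal(r$df, 118)
  expect_equal(r$p, 1.518875e-06, tolerance = 1e-5)
  expect_lte(r$p, 1e-4)
  # plane-equivalence angle summaries: |t| = 1.773, p = 0.079
  r2 <- t_test_from_summary(summary_stats(60, 33.0, 5.3), summary_stats(60, 34.7, 5.2))
  expect_equal(r2$statistic, -1.773497, tolerance = 1e-6)
  expect_equal(r2$p, 0.0787260, tolerance = 1e-6)
  # identical groups
  r3 <- t_test_from_summary(summary_stats(30, 10, 2), summary_stats(30, 10, 2))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p, 1)
})

test_that("raw-sample path agrees with the summary path and with stats::t.test", {
  xs <- c(1, 2, 3, 4); ys <- c(11, 12, 13, 14)
  r <- t_test_from_samples(xs, ys, "student")
  ro <- t_test_from_summary(summarise_sample(xs), summarise_sample(ys), "student")
  expect_equal(r$statistic, ro$statistic, tolerance = 1e-12)
  expect_equal(r$p, ro$p, tolerance = 1e-12)
  expect_equal(summarise_sample(xs)$mean, 2.5)
  expect_equal(summarise_sample(xs)$sd, 1.2909944, tolerance = 1e-7)
  # cross-check against the base implementation on both methods
  set.seed(41)
  for (i in 1:25) {
    a <- rnorm(sample(3:20, 1), 0, 1); b <- rnorm(sample(3:20, 1), 0.5, 2)
    st <- t_test_from_samples(a, b, "student")
    bt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(st$statistic, unname(bt$statistic), tolerance = 1e-10)
    expect_equal(st$p, bt$p.value, tolerance = 1e-10)
    we <- t_test_from_samples(a, b, "welch")
    bw <- stats::t.test(a, b)
    expect_equal(we$df, unname(bw$parameter), tolerance = 1e-10)
    expect_equal(we$p, bw$p.value, tolerance = 1e-10)
  }
  expect_equal(t_test_from_samples(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(t_test_from_samples(1, c(1, 2, 3)), "at least 2")
  # within-group order is irrelevant
  expect_identical(t_test_from_samples(c(3, 1, 2), c(14, 11, 13, 12)),
                   t_test_from_samples(1:3, 11:14))
})

test_that("t test invariances: group swap, scaling, Welch-Student agreement", {
  a <- summary_stats(20, 31.2, 4.1); b <- summary_stats(25, 28.8, 5.6)
  r <- t_test_from_summary(a, b); rs <- t_test_from_summary(b, a)
  expect_equal(rs$statistic, -r$statistic)
  expect_equal(rs$p, r$p)
  k <- 3.7
  rk <- t_test_from_summary(summary_stats(20, k * 31.2, k * 4.1),
                            summary_stats(25, k * 28.8, k * 5.6))
  expect_equal(rk$statistic, r$statistic, tolerance = 1e-12)
  expect_equal(rk$p, r$p, tolerance = 1e-12)
  # equal n and sd: Welch reduces to Student
  e1 <- summary_stats(14, 10, 3); e2 <- summary_stats(14, 12, 3)
  st <- t_test_from_summary(e1, e2, "student")
  we <- t_test_from_summary(e1, e2, "welch")
  expect_equal(we$statistic, st$statistic, tolerance = 1e-9)
  expect_equal(we$p, st$p, tolerance = 1e-9)
  expect_equal(we$df, st$df, tolerance = 1e-9)
})

test_that("degenerate zero-variance groups follow the stated conventions", {
  z <- summary_stats(5, 3, 0)
  expect_equal(t_test_from_summary(z, summary_stats(7, 3, 0))$p, 1)
  expect_warning(r <- t_test_from_summary(z, summary_stats(7, 4, 0)), "zero variance")
  expect_equal(r$p, 0)
})

test_that("Fisher's exact test matches the demographics case and conventions", {
  expect_equal(fisher_exact_2x2(14, 16, 10, 20)$p, 0.4295692, tolerance = 1e-6)
  expect_equal(round(fisher_exact_2x2(14, 16, 10, 20)$p, 2), 0.43)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p equals exhaustive enumeration on all small-margin tables", {
  for (a in 0:12) for (b in 0:(12 - a)) for (c in 0:12) for (d in 0:(12 - c)) {
    if (a + c > 12 || b + d > 12 || a + b + c + d == 0) next
    expect_equal(fisher_exact_2x2(a, b, c, d)$p, fisher_oracle_p(a, b, c, d),
                 tolerance = 1e-12)
  }
})

test_that("minimum sample size matches the closed form and scales as delta^-2", {
  expect_equal(min_sample_size(4.8, 3.9)$n_per_group, 24L)
  expect_equal(min_sample_size(4.8, 3.9)$n_exact, 23.77885, tolerance = 1e-5)
  expect_equal(min_sample_size(4.8, 4.8)$n_per_group, 16L)
  n1 <- min_sample_size(6, 2)$n_exact
  n2 <- min_sample_size(6, 4)$n_exact
  expect_equal(n1 / n2, 4, tolerance = 1e-12)
  expect_error(min_sample_size(4.8, 0), "delta")
})

test_that("the closed-form sample size delivers the nominal power by simulation", {
  # 24 ears/group at sd 4.8, true shift 3.9: empirical power of the Student
  # test over 10^4 replicates should reach ~0.8 (normal-approximation target)
  set.seed(42)
  n <- 24; hits <- 0L; reps <- 10000L
  for (i in seq_len(reps)) {
    x <- rnorm(n, 0, 4.8); y <- rnorm(n, 3.9, 4.8)
    hits <- hits + (t_test_from_samples(x, y)$p < 0.05)
  }
  expect_gte(hits / reps, 0.78)
})

test_that("compare_cohorts mirrors its inputs and flags mixed planes", {
  co_a <- generate_cohort("normal_ci", 30, 7)
  co_b <- generate_cohort("cholesteatoma", 30, 7)
  ma <- measure_cohort(cohort_landmark_sets(co_a), "KC_MFP")
  mb <- measure_cohort(cohort_landmark_sets(co_b), "KC_MFP")
  rep_ <- compare_cohorts(ma, mb, cohort_demographics(co_a), cohort_demographics(co_b),
                          label_a = "CI", label_b = "CH")
  expect_equal(rep_$measures$angle_deg$a$n, 60)
  expect_equal(rep_$measures$angle_deg$b$n, 60)
  expect_lt(rep_$measures$angle_deg$student$p, 0.001)
  expect_lt(rep_$measures$length_mm$student$p, 0.001)
  expect_equal(sum(rep_$demographics$sex$counts), 60)
  expect_match(rep_$provenance$note, "no multiplicity correction")
  # identical cohorts: all p = 1
  same <- compare_cohorts(ma, ma, cohort_demographics(co_a), cohort_demographics(co_a))
  expect_equal(same$measures$angle_deg$student$p, 1)
  expect_equal(same$measures$length_mm$welch$p, 1)
  expect_equal(same$demographics$sex$fisher$p, 1)
  mr <- ma; mr$plane <- "REIDS"
  expect_error(compare_cohorts(ma, mr), "mix plane types")
})
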