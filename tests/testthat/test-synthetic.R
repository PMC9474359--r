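test_that("shipped presets load, validate, and are listed", {
  expect_setequal(list_presets(), shipped_presets)
  for (nm in shipped_presets) {
    p <- load_preset(nm)
    expect_s3_class(p, "cohort_preset")
    expect_gt(p$angle_mean_deg, 0); expect_lt(p$angle_mean_deg, 90)
    expect_gt(p$length_mean_mm, 0)
    expect_true(nzchar(p$provenance))
  }
  expect_error(load_preset("no_such_cohort"), "normal_ci")
  expect_error(cohort_preset("bad", angle_mean_deg = 95, angle_sd_deg = 1,
                             length_mean_mm = 30, length_sd_mm = 1))
})

test_that("zero-jitter generation inverts measurement exactly", {
  for (nm in shipped_presets) {
    co <- generate_cohort(nm, 10, 314)
    m <- measure_cohort(cohort_landmark_sets(co), "KC_MFP")
    tr <- cohort_truth(co)
    expect_equal(m$subject_id, tr$subject_id)
    expect_lt(max(abs(m$angle_deg - tr$angle_deg)), 1e-6)
    expect_lt(max(abs(m$length_mm - tr$length_mm)), 1e-6)
  }
})

test_that("degenerate distributions reproduce the preset means on every ear", {
  p <- cohort_preset("point", angle_mean_deg = 30, angle_sd_deg = 0,
                     length_mean_mm = 35, length_sd_mm = 0)
  co <- generate_cohort(p, 5, 8)
  m <- measure_cohort(cohort_landmark_sets(co), "KC_MFP")
  expect_equal(m$angle_deg, rep(30, 10), tolerance = 1e-9)
  expect_equal(m$length_mm, rep(35, 10), tolerance = 1e-9)
})

test_that("cohorts are reproducible from (preset, n, seed) and order-independent", {
  a <- generate_cohort("normal_ci", 30, 42)
  b <- generate_cohort("normal_ci", 30, 42)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_cohort_json(a, f1); write_cohort_json(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  d <- generate_cohort("normal_ci", 30, 43)
  expect_false(identical(a$subjects[[1]]$landmarks$coords,
                         d$subjects[[1]]$landmarks$coords))
  # subject i does not depend on cohort size
  small <- generate_cohort("normal_ci", 3, 42)
  expect_identical(small$subjects[[3]]$landmarks$coords,
                   a$subjects[[3]]$landmarks$coords)
})

test_that("cohort JSON serialization round-trips losslessly", {
  co <- generate_cohort("cholesteatoma", 4, 77)
  f <- tempfile(fileext = ".json")
  write_cohort_json(co, f)
  co2 <- read_cohort_json(f)
  expect_equal(co2$preset, co$preset)
  expect_equal(co2$seed, co$seed)
  for (i in seq_along(co$subjects)) {
    expect_identical(co2$subjects[[i]]$landmarks$coords,
                     co$subjects[[i]]$landmarks$coords)
    expect_equal(co2$subjects[[i]]$truth, co$subjects[[i]]$truth)
    expect_identical(co2$subjects[[i]]$age_yr, co$subjects[[i]]$age_yr)
  }
})

test_that("measured angle/length distributions match the generating preset", {
  # 10^4 ears from normal_ci at seed 1: mean and sd within 3 standard errors
  p <- load_preset("normal_ci")
  co <- generate_cohort(p, 5000, 1)
  m <- measure_cohort(cohort_landmark_sets(co), "KC_MFP")
  n <- nrow(m)
  expect_equal(nrow(m), 10000)
  expect_lt(abs(mean(m$angle_deg) - p$angle_mean_deg), 3 * p$angle_sd_deg / sqrt(n))
  expect_lt(abs(sd(m$angle_deg) - p$angle_sd_deg), 3 * p$angle_sd_deg / sqrt(2 * n))
  expect_lt(abs(mean(m$length_mm) - p$length_mean_mm), 3 * p$length_sd_mm / sqrt(n))
})

test_that("sample means cover the preset means at the nominal 2-SE rate", {
  # pooled over presets and measures: 2*sd/sqrt(60) covers ~95.4% of replicate
  # means; the pooled empirical coverage over 100 seeds must be >= 93%
  hits <- 0L; total <- 0L
  for (nm in shipped_presets) {
    p <- load_preset(nm)
    for (seed in 1:100) {
      co <- generate_cohort(p, 30, seed)
      tr <- cohort_truth(co)
      hits <- hits +
        (abs(mean(tr$angle_deg) - p$angle_mean_deg) <= 2 * p$angle_sd_deg / sqrt(60)) +
        (abs(mean(tr$length_mm) - p$length_mean_mm) <= 2 * p$length_sd_mm / sqrt(60))
      total <- total + 2L
    }
  }
  expect_gte(hits / total, 0.93)
})

test_that("template tilt shifts the Reid's-plane angle by its nominal amount", {
  # mfp_tilt_deg = 0: the two planes agree in expectation (identically here,
  # all anchors coplanar); with tilt t the mean difference equals t
  p0 <- cohort_preset("tilt0", 33, 5, 32, 3, mfp_tilt_deg = 0)
  co0 <- generate_cohort(p0, 50, 3)
  ls0 <- cohort_landmark_sets(co0)
  d0 <- measure_cohort(ls0, "KC_MFP")$angle_deg - measure_cohort(ls0, "REIDS")$angle_deg
  expect_lt(max(abs(d0)), 1e-9)
  pt <- cohort_preset("tilt2", 33, 5, 32, 3, mfp_tilt_deg = 2)
  cot <- generate_cohort(pt, 1500, 3)
  lst <- cohort_landmark_sets(cot)
  dt <- measure_cohort(lst, "KC_MFP")$angle_deg - measure_cohort(lst, "REIDS")$angle_deg
  # per-ear diff ~ t*cos(phi): sd ~ 0.3*t, so SE of the mean ~ 0.011 deg
  expect_equal(mean(dt), 2, tolerance = 0.05)
})

test_that("rasterized phantoms place labelled balls at the landmark positions", {
  lm <- landmark_set("ph", list(EAC_R = c(0, 0, 0)))
  vol <- rasterize_to_volume(lm, spacing = 1, marker_radius = 2, padding = 2)
  cent <- detect_marker_centroids(vol)
  expect_equal(nrow(cent), 1)
  expect_equal(cent$landmark_id, "EAC_R")
  expect_lt(max(abs(c(cent$x, cent$y, cent$z))), 0.5)

  co <- generate_cohort("normal_ci", 1, 2)
  full <- co$subjects[[1]]$landmarks
  vol2 <- rasterize_to_volume(full, spacing = 0.5, marker_radius = 1.5, padding = 3)
  cent2 <- detect_marker_centroids(vol2)
  expect_equal(nrow(cent2), nrow(full$coords))
  expect_setequal(cent2$landmark_id, rownames(full$coords))
  for (i in seq_len(nrow(cent2))) {
    truth <- full$coords[cent2$landmark_id[i], ]
    expect_lt(distance_mm(c(cent2$x[i], cent2$y[i], cent2$z[i]), truth), 0.25)
  }
})

test_that("rasterization rejects markers too close to stay distinct", {
  lm <- landmark_set("ph", list(PO_R = c(0, 0, 0), TO_R = c(1, 0, 0)))
  expect_error(rasterize_to_volume(lm, spacing = 0.3, marker_radius = 1.5),
               "smaller marker_radius")
  expect_error(rasterize_to_volume(landmark_set("p", list(PO_R = c(0, 0, 0))),
                                   spacing = 1, marker_radius = 0.5),
               "spacing")
})
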