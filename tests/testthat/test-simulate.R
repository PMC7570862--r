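test_that("a 5 s bout at 102.4 Hz has 512 samples per channel", {
  rec <- generate_recording(default_activity_models()$standing,
                            duration_s = 5, sampling_rate = 102.4, seed = 1)
  expect_s3_class(rec, "sensor_recording")
  expect_equal(nrow(rec$acc), 512)
  expect_equal(nrow(rec$gyr), 512)
})

test_that("generation is deterministic under a seed and varies across seeds", {
  m <- default_activity_models()$walking
  a <- generate_recording(m, 2, 102.4, seed = 99)
  b <- generate_recording(m, 2, 102.4, seed = 99)
  c <- generate_recording(m, 2, 102.4, seed = 100)
  expect_identical(a$acc, b$acc)
  expect_identical(a$gyr, b$gyr)
  expect_false(identical(a$acc, c$acc))
})

test_that("invalid durations and rates are rejected", {
  m <- default_activity_models()$standing
  expect_error(generate_recording(m, 0, 102.4, seed = 1), "duration")
  expect_error(generate_recording(m, 5, -1, seed = 1), "sampling_rate")
  expect_error(study_protocol(continuous_duration_s = 0), "duration")
  expect_error(study_protocol(transitional_repeats = 0), "repeats")
})

test_that("static recordings have lower variance than dynamic ones", {
  models <- default_activity_models()
  for (seed in 1:10) {
    v_static <- mean(apply(generate_recording(models$standing, 5, 102.4, seed)$acc, 2, var))
    v_dynamic <- mean(apply(generate_recording(models$walking, 5, 102.4, seed)$acc, 2, var))
    expect_lt(v_static, v_dynamic)
  }
})

test_that("per-window variance orders static < transitional plateau < dynamic", {
  models <- default_activity_models()
  mean_var <- function(rec, rows = seq_len(nrow(rec$acc))) {
    mean(c(apply(rec$acc[rows, ], 2, var), apply(rec$gyr[rows, ], 2, var)))
  }
  static <- dynamic <- plateau <- numeric(10)
  for (seed in 1:10) {
    static[seed] <- mean_var(generate_recording(models$sleeping, 8, 102.4, seed))
    dynamic[seed] <- mean_var(generate_recording(models$running, 8, 102.4, seed))
    ## first 2 s of an 8 s transitional bout sit on the start hold
    trans <- generate_recording(models$lie_to_sit, 8, 102.4, seed)
    plateau[seed] <- mean_var(trans, rows = 1:205)
  }
  expect_lt(mean(static), mean(plateau))
  expect_lt(mean(plateau), mean(dynamic))
})

test_that("transitional bouts ramp monotonically between the two postures", {
  m <- activity_model("sit_to_stand",
    baseline = c(0, 0.6, 0.8, 0, 0, 0),
    end_baseline = c(0, 0, 1, 0, 0, 0),
    noise_sd = rep(0, 6), ramp_s = 3
  )
  rec <- generate_recording(m, 8, 102.4, seed = 1)
  y <- rec$acc[, 2] # 0.6 -> 0 without noise
  expect_true(all(diff(y) <= 1e-12))
  expect_equal(y[1], 0.6, tolerance = 1e-3)
  expect_equal(y[length(y)], 0, tolerance = 1e-3)
})

test_that("generate_study emits one recording per subject/activity/repeat", {
  proto <- study_protocol(
    n_subjects = 2, continuous_duration_s = 20,
    transitional_repeats = 3, seed = 3
  )
  recs <- generate_study(proto)
  expect_length(recs, 2 * (6 * 1 + 6 * 3))
  standing <- Filter(function(r) r$activity == "standing", recs)
  expect_length(standing, 2)
  expect_equal(nrow(standing[[1]]$acc), round(20 * 102.4))

  expect_length(generate_study(study_protocol(n_subjects = 0)), 0)
  expect_error(
    generate_study(proto, default_activity_models()[-1]),
    "missing activity model"
  )
})

test_that("study regeneration from the same master seed is identical", {
  proto <- study_protocol(n_subjects = 1, continuous_duration_s = 10,
                          transitional_repeats = 2, seed = 77)
  a <- generate_study(proto)
  b <- generate_study(proto)
  expect_identical(
    lapply(a, function(r) r$acc), lapply(b, function(r) r$acc)
  )
})

test_that("default protocol class imbalance matches the intended ~5:1 ratio", {
  ## 2 subjects at the default bout schedule; counts scale linearly in
  ## subjects, so ratios match the full 10-subject study
  proto <- study_protocol(n_subjects = 2)
  counts <- class_counts(segment_recordings(generate_study(proto)))
  continuous <- counts["standing"]
  transitional <- counts["stand_to_sit"]
  expect_equal(unname(continuous / transitional), 1198 / 239, tolerance = 0.1)
  groups <- activity_group(names(counts))
  expect_true(all(counts[groups != "transitional"] == continuous))
  expect_true(all(counts[groups == "transitional"] == transitional))
})

test_that("static models reject oscillation and transitional models need a ramp", {
  expect_error(
    activity_model("standing", amplitude = rep(1, 6)),
    "zero oscillation"
  )
  expect_error(
    activity_model("sit_to_lie", end_baseline = numeric(6), ramp_s = 0),
    "ramp_s"
  )
  expect_error(activity_model("standing", noise_sd = rep(-1, 6)), "noise_sd")
})
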