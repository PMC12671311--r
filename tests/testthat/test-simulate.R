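test_that("config validation names the offending field", {
  expect_error(sim_config(n_participants = 1), "n_participants")
  expect_error(sim_config(artifact_rate = 0.6), "artifact_rate")
  expect_error(sim_config(fraction_ms = 1.2), "fraction_ms")
  expect_error(sim_config(effect_vector = c(0.3)), "named")
})

test_that("stream simulation is deterministic given the seed", {
  cfg <- sim_config(n_participants = 2, n_days = 2, seed = 31)
  a <- suppressWarnings(simulate_cohort(cfg))
  b <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(a, b)
})

test_that("artifact_rate 0 produces an empty truth artifact set", {
  cfg <- sim_config(n_participants = 2, n_days = 2, artifact_rate = 0, seed = 8)
  co <- suppressWarnings(simulate_cohort(cfg))
  expect_equal(nrow(co$truth$artifacts), 0)
})

test_that("nocturnal bradycardia matches the configured dip and HRV gain raises night SD1", {
  cfg <- sim_config(n_participants = 2, n_days = 3, hr_night_dip = 15, seed = 12)
  co <- suppressWarnings(simulate_cohort(cfg))
  for (id in co$participants$id) {
    st <- co$streams[[id]]
    bw <- co$truth$bed_wake[co$truth$bed_wake$participant == id, ]
    night <- rep(FALSE, nrow(st$hr))
    for (d in seq_len(nrow(bw))) {
      # plateau region, clear of the 30-min transition ramps
      night <- night | (st$hr$time_s > bw$bed_time[d] + 1800 &
                          st$hr$time_s < bw$wake_time[d] - 1800)
    }
    day <- !night
    for (d in seq_len(nrow(bw))) {
      day <- day & !(st$hr$time_s > bw$bed_time[d] - 1800 &
                       st$hr$time_s < bw$wake_time[d] + 1800)
    }
    dip_hat <- mean(st$hr$hr_bpm[day]) - mean(st$hr$hr_bpm[night])
    expect_lt(abs(dip_hat - 15), 2.5)
    expect_lt(mean(st$hr$hr_bpm[night]), mean(st$hr$hr_bpm[day]))

    # windowed SD1 higher at night in expectation
    w <- filter_windows(window_series(st$ibi))
    mid <- (w$start + w$end) / 2
    wn <- rep(FALSE, nrow(w))
    for (d in seq_len(nrow(bw))) {
      wn <- wn | (w$start > bw$bed_time[d] & w$end < bw$wake_time[d])
    }
    expect_gt(mean(w$sd1[wn & w$kept], na.rm = TRUE),
              mean(w$sd1[!wn & w$kept], na.rm = TRUE))
  }
})

test_that("steps are zero during true sleep except configured bouts", {
  cfg <- sim_config(n_participants = 2, n_days = 2, bathroom_prob = 0, seed = 19)
  co <- suppressWarnings(simulate_cohort(cfg))
  for (id in co$participants$id) {
    st <- co$streams[[id]]
    bw <- co$truth$bed_wake[co$truth$bed_wake$participant == id, ]
    for (d in seq_len(nrow(bw))) {
      asleep <- st$steps$time_s > bw$bed_time[d] & st$steps$time_s < bw$wake_time[d]
      expect_equal(sum(st$steps$steps[asleep]), 0)
    }
  }
})

test_that("response generator obeys the stated logistic model", {
  set.seed(5)
  feats <- data.frame(participant = rep("a", 400), f1 = rnorm(400), f2 = rnorm(400))

  # null effects: label frequency near 1/2, independent of features
  r0 <- simulate_responses(feats, c(f1 = 0), seed = 1)
  expect_lt(abs(mean(r0$label) - 0.5), 0.08)

  # one dominant coefficient with tiny noise: labels follow the feature sign
  r1 <- simulate_responses(feats, c(f1 = 5), noise_sd = 0.01, seed = 2)
  expect_identical(r1$label, as.integer(feats$f1 > 0))

  # determinism and error handling
  expect_identical(simulate_responses(feats, c(f1 = 1), seed = 9),
                   simulate_responses(feats, c(f1 = 1), seed = 9))
  expect_error(simulate_responses(feats, c(nope = 1)), "valid names")
})

test_that("ratings discretize the latent monotonically and binarize back to the labels", {
  co <- simulate_feature_cohort(sim_config(seed = 23))
  norm <- suppressWarnings(normalize_per_participant(co$features))
  y <- binarize_sleep_quality(norm$data$sleep_quality)
  ok <- !is.na(y)
  agree <- mean(y[ok] == co$truth$label[ok])
  expect_gt(agree, 0.8)
})

test_that("feature-level generator reproduces the configured marginals", {
  cfg <- sim_config(seed = 40)
  co <- simulate_feature_cohort(cfg)
  f <- co$features
  n <- nrow(f)
  # mean stress within 3 SE of the configured participant-mean midpoint
  se_stress <- sd(f$mean_stress_awake) / sqrt(length(unique(f$participant)))
  expect_lt(abs(mean(f$mean_stress_awake) - mean(cfg$stress_mean_range)),
            3 * se_stress)
  # sleep duration centred on its population value
  se_sd <- sd(f$sleep_duration) / sqrt(length(unique(f$participant)))
  expect_lt(abs(mean(f$sleep_duration) - 7.3), 3 * se_sd)
  # diary scales respect their ranges
  expect_true(all(f$sleep_quality %in% 1:5))
  expect_true(all(f$mean_stress_awake >= 1 & f$mean_stress_awake <= 10))
  expect_identical(co, simulate_feature_cohort(cfg))
})

test_that("stream cohort diaries and stress logs respect their scales", {
  co <- small_stream_cohort()
  expect_true(all(co$diary$sleep_quality %in% 1:5))
  expect_true(all(co$stress$stress >= 1 & co$stress$stress <= 10))
  # every participant-day has streams covering the true sleep period
  for (id in co$participants$id) {
    st <- co$streams[[id]]
    bw <- co$truth$bed_wake[co$truth$bed_wake$participant == id, ]
    expect_true(min(st$hr$time_s) <= min(bw$bed_time))
    expect_true(max(st$hr$time_s) >= max(bw$wake_time))
  }
})
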