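test_that("daily aggregates and ratios match hand computation and a fold oracle", {
  a <- aggregate_day(c(50, 100, 150))
  expect_equal(unname(a), c(50, 100, 150, 0.5, 1.5))
  single <- aggregate_day(7)
  expect_equal(unname(single), c(7, 7, 7, 1, 1))
  expect_true(all(is.na(aggregate_day(numeric(0)))))

  set.seed(3)
  for (i in 1:25) {
    v <- runif(sample(1:30, 1), 1, 100)
    a <- aggregate_day(v)
    # brute-force fold
    mn <- v[1]; mx <- v[1]; s <- 0
    for (x in v) { mn <- min(mn, x); mx <- max(mx, x); s <- s + x }
    expect_equal(unname(a),
                 c(mn, s / length(v), mx, mn / (s / length(v)), mx / (s / length(v))),
                 tolerance = 1e-12)
    expect_true(a[["minimum"]] <= a[["mean"]] && a[["mean"]] <= a[["maximum"]])
    expect_true(a[["minimum_ratio"]] <= 1 && a[["maximum_ratio"]] >= 1)
  }
})

test_that("static covariates binarize at the 3/3/4/17 cutoffs with strict >", {
  p <- data.frame(id = c("a", "b", "c"),
                  group = c("MS", "MS", "control"),
                  edss = c(3.5, 3.0, 6), msss = c(3.1, 3.0, 9),
                  armss = c(4.5, 4.0, 8), compass = c(18, 17, 40))
  out <- binarize_static(p)
  expect_identical(out$edss_severe, c(TRUE, FALSE, FALSE))
  expect_identical(out$msss_severe, c(TRUE, FALSE, FALSE))
  expect_identical(out$armss_severe, c(TRUE, FALSE, FALSE))
  expect_identical(out$ans_dysfunction, c(TRUE, FALSE, FALSE))
  # control participant's recorded scores are zeroed before the rule
  expect_false(any(out[out$group != "MS", c("edss_severe", "msss_severe",
                                            "armss_severe", "ans_dysfunction")] == TRUE))
  p$edss[1] <- -1
  expect_error(binarize_static(p), "non-negative")
})

test_that("stress aggregation averages the day's logs", {
  expect_equal(aggregate_stress(c(2, 4, 6)), 4)
  expect_equal(aggregate_stress(7), 7)
  expect_true(is.na(aggregate_stress(numeric(0))))
  expect_error(aggregate_stress(c(3, 11)), "1..10")
})

test_that("wake-anchored day splitting assigns windows to one day and state", {
  # two nights: bed 23:00/wake 07:00, bed 22:30/wake 06:30 next day
  p1 <- sleep_period(23 * 3600, 31 * 3600)
  p2 <- sleep_period(86400 + 22.5 * 3600, 2 * 86400 + 6.5 * 3600)
  day_starts <- c(7 * 3600, p1$wake_time)
  w <- window_series(ibi_series(seq(7 * 3600, 2 * 86400 + 7 * 3600, by = 1),
                                rep(1000, 2 * 86400 + 1)))
  out <- split_day(filter_windows(w), list(p1, p2), day_starts)

  # a window wholly inside the trimmed analysis bounds is asleep
  mid_night <- out$start > p1$analysis_start + 300 & out$end < p1$analysis_end - 300
  expect_true(all(out$state[mid_night] == "asleep"))
  expect_true(all(out$day[mid_night] == 1))
  # afternoon windows of day 1 are awake
  aft <- out$start > 12 * 3600 & out$end < 20 * 3600
  expect_true(all(out$state[aft] == "awake"))
  # the first hour after going to bed is assigned to neither state
  tz <- out$start >= p1$bed_time & out$end <= p1$bed_time + 3600
  expect_true(all(out$state[tz] == "trimmed"))
  # partition: every in-day window has exactly one state; states are disjoint
  assigned <- !is.na(out$day)
  expect_true(all(out$state[assigned] %in% c("awake", "asleep", "trimmed")))
  expect_true(all(is.na(out$state[!assigned])))

  expect_error(split_day(out, list(p1, sleep_period(25 * 3600, 33 * 3600)),
                         day_starts), "overlapping")
})

test_that("the daily feature table respects aggregate invariants and explicit missingness", {
  co <- small_stream_cohort()
  feats <- suppressWarnings(build_daily_features(co, use_truth_periods = TRUE))
  expect_equal(nrow(feats), nrow(co$participants) * co$config$n_days)

  for (v in c("hr", "sd1", "sd2", "sdnn")) {
    for (st in c("awake", "asleep")) {
      mn <- feats[[paste0("minimum_", v, "_", st)]]
      me <- feats[[paste0("mean_", v, "_", st)]]
      mx <- feats[[paste0("maximum_", v, "_", st)]]
      ok <- !is.na(mn)
      expect_true(all(mn[ok] <= me[ok] + 1e-12 & me[ok] <= mx[ok] + 1e-12))
      rlo <- feats[[paste0(v, "_minimum_ratio_", st)]]
      rhi <- feats[[paste0(v, "_maximum_ratio_", st)]]
      expect_true(all(rlo[ok] <= 1 + 1e-12 & rhi[ok] >= 1 - 1e-12))
      expect_true(all(rlo[ok] > 0))
    }
  }
  # no NaN-by-accident: every cell is a number or an explicit NA
  num <- vapply(feats, is.numeric, TRUE)
  expect_false(any(vapply(feats[num], function(cl) any(is.nan(cl)), TRUE)))
  # diary columns carried through
  expect_true(all(feats$sleep_quality %in% 1:5))
  expect_true(all(feats$sleep_duration > 0))
})
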