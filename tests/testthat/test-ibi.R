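test_that("Poincare descriptors match hand-computable cases", {
  expect_equal(unname(poincare_metrics(rep(800, 4))), c(0, 0, 0))
  m <- poincare_metrics(c(800, 600, 800, 600, 800))
  expect_equal(unname(m["sd1"]), 200 / sqrt(2))
  expect_equal(unname(m["sd2"]), 0)
  expect_error(poincare_metrics(c(800, 810)), "fewer than 3")
})

test_that("successive-difference formulation equals the geometric point-to-line oracle", {
  set.seed(101)
  for (i in 1:50) {
    ibi <- 800 + cumsum(rnorm(sample(5:400, 1), 0, 20))
    ibi <- pmax(ibi, 300)
    expect_equal(unname(poincare_metrics(ibi)),
                 unname(oracle_poincare_geometric(ibi)),
                 tolerance = 1e-12)
  }
})

test_that("sd1^2 + sd2^2 approximates 2 sdnn^2 on long stationary windows", {
  set.seed(77)
  for (i in 1:10) {
    z <- as.numeric(stats::filter(rnorm(400, 0, 10), 0.6, method = "recursive"))
    ibi <- 800 + z[101:400]
    m <- poincare_metrics(ibi)
    expect_equal(m[["sd1"]]^2 + m[["sd2"]]^2, 2 * m[["sdnn"]]^2,
                 tolerance = 0.05)
  }
})

test_that("artifact detection flags deviant beats and nothing on clean data", {
  clean <- ibi_series(cumsum(rep(0.8, 60)), rep(800, 60))
  expect_false(any(detect_artifacts(clean)))

  ib <- rep(800, 60)
  ib[30] <- 1600  # missed beat: one interval absorbs its successor
  miss <- ibi_series(cumsum(ib) / 1000, ib)
  mask <- detect_artifacts(miss)
  expect_identical(which(mask), 30L)
  expect_identical(mask, oracle_detect(ib))

  expect_error(detect_artifacts(ibi_series(cumsum(rep(0.8, 5)), rep(800, 5))),
               "at least")
})

test_that("detection matches the brute-force sliding-median rule on noisy series", {
  set.seed(55)
  for (i in 1:20) {
    ibi <- pmax(300, 800 + as.numeric(
      stats::filter(rnorm(300, 0, 15), 0.7, method = "recursive")))
    hit <- sample(20:280, 3)
    ibi[hit] <- ibi[hit] * sample(c(0.5, 2), 3, replace = TRUE)
    s <- ibi_series(cumsum(ibi) / 1000, ibi)
    expect_identical(detect_artifacts(s), oracle_detect(ibi))
  }
})

test_that("detector recovers injected artifacts on the synthetic stress cohort", {
  co <- suppressWarnings(
    simulate_cohort(sim_config(n_participants = 2, n_days = 2,
                               artifact_rate = 0.02, seed = 11)))
  sens <- fpr <- numeric(0)
  for (id in co$participants$id) {
    st <- co$streams[[id]]
    mask <- detect_artifacts(st$ibi)
    truth_t <- co$truth$artifacts$time_s[co$truth$artifacts$participant == id]
    flagged_t <- st$ibi$time_s[mask]
    hit <- vapply(truth_t, function(a) any(abs(flagged_t - a) <= 2), TRUE)
    near <- vapply(st$ibi$time_s, function(b) {
      i <- findInterval(b, truth_t)
      any(abs(b - truth_t[pmax(1, c(i, i + 1))]) <= 2, na.rm = TRUE)
    }, TRUE)
    sens <- c(sens, mean(hit))
    fpr <- c(fpr, sum(mask & !near) / sum(!near))
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fpr), 0.02)
})

test_that("interpolation is linear between valid neighbours and idempotent", {
  s <- ibi_series(c(0.8, 1.6, 2.4), c(800, 999, 800))
  out <- interpolate_artifacts(s, c(FALSE, TRUE, FALSE))
  expect_equal(out$ibi_ms[2], 800)
  expect_identical(out$flag, c("valid", "interpolated", "valid"))

  s2 <- ibi_series(c(0.6, 1.3, 2.1), c(600, 999, 800))
  expect_equal(interpolate_artifacts(s2, c(FALSE, TRUE, FALSE))$ibi_ms[2], 700)

  expect_identical(interpolate_artifacts(s, rep(FALSE, 3)), s)
  expect_error(interpolate_artifacts(s, rep(TRUE, 3)), "every beat")

  # detect -> interpolate -> detect again changes nothing the second time
  co <- small_stream_cohort()
  st <- co$streams[[co$participants$id[1]]]
  sub <- ibi_series(st$ibi$time_s[1:5000], st$ibi$ibi_ms[1:5000])
  m1 <- detect_artifacts(sub)
  clean <- interpolate_artifacts(sub, m1)
  m2 <- detect_artifacts(clean)
  clean2 <- interpolate_artifacts(clean, m2)
  expect_equal(clean2$ibi_ms, interpolate_artifacts(clean2, detect_artifacts(clean2))$ibi_ms)
})

test_that("windows tile the recording and each beat lands in exactly one", {
  s <- ibi_series(seq(0, 1000, by = 1), rep(1000, 1001))
  expect_equal(nrow(window_series(s)), 3)
  s300 <- ibi_series(seq(0, 300, by = 1), rep(1000, 301))
  expect_equal(nrow(window_series(s300)), 1)
  short <- ibi_series(seq(0, 200, by = 1), rep(1000, 201))
  expect_equal(nrow(window_series(short)), 0)

  set.seed(13)
  for (i in 1:10) {
    ibi <- pmax(300, rnorm(2000, 800, 50))
    s <- ibi_series(cumsum(ibi) / 1000, ibi)
    w <- window_series(s)
    in_win <- vapply(s$time_s, function(t) {
      sum(t >= w$start & t < w$end)
    }, 0L)
    covered <- s$time_s < max(w$end)
    expect_true(all(in_win[covered] == 1L))
    expect_true(all(in_win[!covered] == 0L))
    expect_equal(sum(w$n_beats), sum(covered))
  }
})

test_that("window metrics are invariant to a constant timestamp offset", {
  set.seed(21)
  ibi <- pmax(300, rnorm(1500, 800, 40))
  a <- window_series(ibi_series(cumsum(ibi) / 1000, ibi))
  b <- window_series(ibi_series(cumsum(ibi) / 1000 + 98765, ibi))
  expect_equal(a[, c("n_beats", "mean_hr", "sd1", "sd2", "sdnn")],
               b[, c("n_beats", "mean_hr", "sd1", "sd2", "sdnn")])
})

test_that("the interpolated-beat exclusion rule keeps at most 4 per window", {
  w <- data.frame(start = 0, end = 300, n_beats = 300,
                  n_interpolated = c(0L, 4L, 5L, 9L),
                  mean_hr = 70, sd1 = 1, sd2 = 1, sdnn = 1, kept = NA)
  out <- filter_windows(w)
  expect_identical(out$kept, c(TRUE, TRUE, FALSE, FALSE))
})
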