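test_that("rank test handles the canonical small cases exactly", {
  same <- rank_sum_test(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$p_value, 1.0)

  sep <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, 0.1)  # 2 of the C(6,3) = 20 labelings are as extreme

  expect_error(rank_sum_test(numeric(0), c(1, 2)), "non-empty")
})

test_that("exact p equals the full-permutation oracle, ties included", {
  set.seed(70)
  for (i in 1:40) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    vals <- sample(1:5, n1 + n2, replace = TRUE)  # heavy ties, Likert-like
    g1 <- vals[seq_len(n1)]; g2 <- vals[-seq_len(n1)]
    expect_equal(rank_sum_test(g1, g2)$p_value, oracle_ranksum_perm(g1, g2),
                 tolerance = 1e-12)
  }
})

test_that("exact path agrees with wilcox.test when there are no ties", {
  set.seed(71)
  for (i in 1:20) {
    g1 <- rnorm(sample(3:6, 1)); g2 <- rnorm(sample(3:6, 1))
    ours <- rank_sum_test(g1, g2)
    ref <- stats::wilcox.test(g1, g2, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(72)
  g1 <- sample(1:5, 30, replace = TRUE)
  g2 <- sample(1:5, 25, replace = TRUE) + 0.5
  ours <- rank_sum_test(g1, g2)
  ref <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE, correct = FALSE))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_match(ours$method, "normal")
})

test_that("a simulated severity shift is detected with adequate power", {
  # participant-level mean scores: severe subgroup 0.4 points lower, spread
  # matching the generator's between-participant dispersion of mean ratings
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    g1 <- rnorm(35, 3.85, 0.45)
    g2 <- rnorm(25, 3.45, 0.45)
    rank_sum_test(g1, g2)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("subgroup report reduces to participants first and matches a fold oracle", {
  co <- simulate_feature_cohort(sim_config(seed = 80))
  profiles <- binarize_static(co$participants)
  daily <- co$features
  rep_all <- subgroup_report(daily, profiles)
  expect_true(all(c("comparison", "n1", "mean1", "sd1", "n2", "mean2", "sd2",
                    "p_value") %in% names(rep_all)))
  expect_true(all(rep_all$p_value >= 0 & rep_all$p_value <= 1))

  # independent two-pass fold for one row: disease status
  sq <- vapply(split(daily$sleep_quality, daily$participant), mean, 0)
  ms_ids <- profiles$id[profiles$group == "MS"]
  m2 <- sum(sq[ms_ids]) / length(ms_ids)
  row <- rep_all[rep_all$comparison == "disease status", ]
  expect_equal(row$mean2, m2, tolerance = 1e-12)
  expect_equal(row$n2, length(ms_ids))

  # a predicate matching nobody is skipped with a warning
  specs <- list(subgroup_spec("impossible", function(p) p$age > 500, "all"))
  expect_warning(out <- subgroup_report(daily, profiles, specs), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("correlation matrices are symmetric with unit diagonal and exact r", {
  set.seed(81)
  df <- data.frame(x = rnorm(40))
  df$y <- 2 * df$x
  df$z <- rnorm(40)
  cm <- correlation_matrix(df)[["all"]]
  expect_equal(cm$r["x", "x"], 1.0)
  expect_equal(cm$r["x", "y"], 1.0)
  expect_lt(cm$p["x", "y"], 1e-12)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))

  # covariance-formula oracle
  r_oracle <- sum((df$x - mean(df$x)) * (df$z - mean(df$z))) /
    sqrt(sum((df$x - mean(df$x))^2) * sum((df$z - mean(df$z))^2))
  expect_equal(cm$r["x", "z"], r_oracle, tolerance = 1e-12)
  ref <- stats::cor.test(df$x, df$z)
  expect_equal(cm$p["x", "z"], ref$p.value, tolerance = 1e-12)

  # per-group computation really separates the groups
  grp <- rep(c("A", "B"), each = 20)
  cg <- correlation_matrix(df, group = grp)
  expect_named(cg, c("A", "B"))
  expect_false(isTRUE(all.equal(cg$A$r["x", "z"], cg$B$r["x", "z"])))
})

test_that("proportion sample size reproduces the design value and its structure", {
  expect_identical(sample_size_for_proportion(0.85, 0.10, 0.95), 49L)
  expect_identical(suppressWarnings(sample_size_for_proportion(0.5, 0.5, 0.95)), 4L)

  # halving the half-width about quadruples n
  n1 <- sample_size_for_proportion(0.7, 0.10, 0.95)
  n2 <- sample_size_for_proportion(0.7, 0.05, 0.95)
  expect_true(n2 >= 3.8 * n1 && n2 <= 4.2 * n1)

  # monotone in halfwidth and confidence
  hw <- c(0.02, 0.05, 0.1, 0.2)
  ns <- vapply(hw, function(h) suppressWarnings(sample_size_for_proportion(0.85, h, 0.95)), 0L)
  expect_true(all(diff(ns) <= 0))
  cf <- c(0.8, 0.9, 0.95, 0.99)
  ns2 <- vapply(cf, function(cc) sample_size_for_proportion(0.85, 0.1, cc), 0L)
  expect_true(all(diff(ns2) >= 0))

  expect_error(sample_size_for_proportion(0, 0.1, 0.95), "'p'")
  expect_warning(sample_size_for_proportion(0.95, 0.2, 0.95), "half-width")
})
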