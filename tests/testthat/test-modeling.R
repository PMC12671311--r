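test_that("per-participant normalization is an invertible z-score", {
  df <- data.frame(participant = rep(c("a", "b"), each = 3),
                   sleep_quality = c(3, 4, 5, 2, 2, 2),
                   x = c(10, 20, 30, 1, 2, 4))
  norm <- suppressWarnings(normalize_per_participant(df))
  expect_equal(norm$data$sleep_quality[1:3], c(-1, 0, 1))
  # constant column for b dropped and recorded
  expect_true(all(is.na(norm$data$sleep_quality[4:6])))
  expect_true(any(norm$dropped$participant == "b" &
                    norm$dropped$column == "sleep_quality"))
  # round trip
  back <- denormalize(norm)
  expect_equal(back$x, df$x, tolerance = 1e-12)

  # within-participant mean 0 / SD 1 at tight tolerance
  set.seed(14)
  big <- data.frame(participant = rep(sprintf("p%02d", 1:8), each = 14),
                    v = rnorm(112), w = runif(112))
  nb <- normalize_per_participant(big)
  for (u in unique(big$participant)) {
    sel <- nb$data$participant == u
    expect_lt(abs(mean(nb$data$v[sel])), 1e-9)
    expect_lt(abs(sd(nb$data$v[sel]) - 1), 1e-9)
  }
})

test_that("participants with a single day are dropped with a warning", {
  df <- data.frame(participant = c("a", "a", "b"), x = c(1, 2, 9))
  expect_warning(norm <- normalize_per_participant(df), "fewer than 2")
  expect_true(all(is.na(norm$data$x[norm$data$participant == "b"])))
})

test_that("binarization is strict: better than the personal average only", {
  expect_identical(binarize_sleep_quality(c(0.3, 0, -0.2, NA)),
                   c(1L, 0L, 0L, NA_integer_))
  set.seed(2)
  z <- rnorm(200)
  expect_equal(sum(binarize_sleep_quality(z)), sum(z > 0))
})

test_that("normality check behaves as a calibrated Shapiro-Wilk gate", {
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    check_response_normality(rnorm(500))$p_value > 0.05
  }, TRUE)
  expect_gte(mean(ok), 0.9)

  set.seed(1)
  disc <- sample(1:5, 500, replace = TRUE, prob = c(.05, .1, .3, .4, .15))
  res <- check_response_normality(scale(disc)[, 1])
  expect_lt(res$p_value, 0.001)
  expect_false(res$normal)

  expect_error(check_response_normality(c(1, 2)), "at least 3")
  expect_error(check_response_normality(rep(1, 10)), "constant")
})

test_that("L1 fit selects a strong feature among noise and reports a refit", {
  recovered <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 300
    x <- as.data.frame(matrix(rnorm(n * 11), n,
                              dimnames = list(NULL, c("signal", paste0("n", 1:10)))))
    y <- rbinom(n, 1, plogis(1.5 * x$signal))
    f <- fit_l1_logistic(x, y)
    "signal" %in% f$selected && f$coefficients[["signal"]] > 0
  }, TRUE)
  expect_gte(mean(recovered), 0.95)
})

test_that("L1 fit shrinks everything to zero on pure noise", {
  set.seed(4)
  n <- 800
  x <- as.data.frame(matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("v", 1:10))))
  y <- rbinom(n, 1, 0.5)
  f <- fit_l1_logistic(x, y)
  expect_length(f$selected, 0)
})

test_that("duplicating every row leaves the penalized path unchanged", {
  set.seed(6)
  x <- as.data.frame(matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c"))))
  y <- rbinom(200, 1, plogis(x$a))
  f1 <- fit_l1_logistic(x, y, penalty = 0.05)
  f2 <- fit_l1_logistic(rbind(x, x), c(y, y), penalty = 0.05)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
})

test_that("degenerate modelling inputs raise informative errors", {
  x <- data.frame(a = rnorm(20))
  expect_error(fit_l1_logistic(x, rep(1, 20), penalty = 0.1), "single class")
  x$a[3] <- NA
  expect_error(fit_l1_logistic(x, rep(0:1, 10), penalty = 0.1), "missing cells")
})

test_that("sequential forward selection finds the informative feature first", {
  set.seed(8)
  n <- 280
  id <- rep(sprintf("p%02d", 1:20), each = 14)
  x <- as.data.frame(matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("z", 1:8))))
  x$signal <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.6 * x$signal))
  sel <- sequential_feature_selection(x, y, groups = id, seed = 8)
  expect_identical(sel[1], "signal")

  # invariance to column order (ties broken lexicographically)
  sel2 <- sequential_feature_selection(x[, rev(names(x))], y, groups = id, seed = 8)
  expect_identical(as.character(sel), as.character(sel2))

  # all-noise candidates: nothing (or nothing useful) gets picked
  xn <- x[, setdiff(names(x), "signal")]
  seln <- sequential_feature_selection(xn, y, groups = id, seed = 8)
  if (length(seln) > 0) {
    expect_lte(max(attr(seln, "auc_path")), 0.55)
  } else {
    expect_length(seln, 0)
  }
  expect_error(sequential_feature_selection(x[, 0], y, groups = id), "empty")
})

test_that("model family scopes, M2 inheritance and group handling are consistent", {
  md <- prep_model_data(sim_config(n_participants = 30, seed = 17))
  norm <- md$norm
  grp <- md$cohort$participants$group[match(norm$data$participant,
                                            md$cohort$participants$id)]

  f1 <- fit_model_family(norm, family = "M1")
  # day-scope fit sees no night-derived columns
  day_fit <- f1[["M1.3"]]
  expect_false(any(endsWith(day_fit$feature_names, "_asleep")))
  expect_false(any(day_fit$feature_names %in%
                     c("sleep_duration", "awake_at_night")))
  night_fit <- f1[["M1.2"]]
  expect_false(any(endsWith(night_fit$feature_names, "_awake")))

  f2 <- fit_model_family(norm, scope = "night", family = "M2", group = grp)
  base <- fit_model_family(norm, scope = "night", family = "M1")[["M1.2"]]
  for (f in f2) expect_setequal(f$selected, base$selected)

  expect_error(fit_model_family(norm, scope = "night", family = "M3",
                                group = grp, min_group_participants = 100),
               "participants")
})

test_that("effect signs stay stable from the joint fit to group refits", {
  md <- prep_model_data(sim_config(seed = 29))
  norm <- md$norm
  grp <- md$cohort$participants$group[match(norm$data$participant,
                                            md$cohort$participants$id)]
  f1 <- fit_model_family(norm, scope = "both", family = "M1")[["M1.1"]]
  f2 <- fit_model_family(norm, scope = "both", family = "M2", group = grp)
  shared <- names(md$cohort$truth$effect_vector)
  strong <- shared[abs(md$cohort$truth$effect_vector) >= 0.4]
  for (f in f2) {
    common <- intersect(intersect(strong, names(f$coefficients)),
                        names(f1$coefficients))
    expect_true(all(sign(f$coefficients[common]) == sign(f1$coefficients[common])))
  }
})

test_that("selected-feature count is non-increasing in penalty strength", {
  md <- prep_model_data(sim_config(n_participants = 30, seed = 33))
  counts <- vapply(c(0.001, 0.01, 0.05, 0.1, 0.3), function(lam) {
    length(fit_l1_logistic(md$dat[md$cols], md$dat$label, penalty = lam)$selected)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("fit methods print, summarise and predict coherently", {
  md <- prep_model_data(sim_config(n_participants = 30, seed = 3))
  f <- fit_l1_logistic(md$dat[md$cols], md$dat$label)
  expect_output(print(f), "slq_fit")
  s <- summary(f)
  expect_true(all(s$table$p_value >= 0 & s$table$p_value <= 1))
  p <- predict(f, md$dat[md$cols])
  expect_true(all(p >= 0 & p <= 1))
  cls <- predict(f, md$dat[md$cols], type = "class")
  expect_identical(cls, as.integer(p > 0.5))
})
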