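#' Resting-window rule
#'
#' A 5-minute window counts as resting when its mean heart rate is strictly
#' below 0.55 x (220 - age) bpm, the eligibility rule for
#' photoplethysmography-based HRV analysis. Only resting windows feed the
#' daily HRV aggregates.
#'
#' @param mean_hr window mean heart rate, bpm (vectorised).
#' @param age participant age in years, 0 < age < 120.
#' @param coef,hr_ceiling rule constants, defaults 0.55 and 220 bpm.
#' @return Logical, \code{TRUE} where the window is resting.
#' @export
#' @examples
#' classify_resting(100, age = 20)  # threshold 110 -> TRUE
#' classify_resting(88, age = 60)   # threshold 88, strict -> FALSE
classify_resting <- function(mean_hr, age, coef = 0.55, hr_ceiling = 220) {
  stopifnot_scalar(age, "age", 0, 120, strict_lo = TRUE, strict_hi = TRUE)
  if (any(mean_hr <= 0, na.rm = TRUE)) stop("'mean_hr' must be positive")
  mean_hr < coef * (hr_ceiling - age)
}

#' Construct a sleep period with transition trimming
#'
#' Stores estimated going-to-bed and wake-up times and the analysis bounds
#' obtained by trimming \code{trim_h} hours (default 1) after bed time and
#' before wake time, excluding the transitional falling-asleep and waking
#' states. Periods left with no interior after trimming are unusable.
#'
#' @param bed_time,wake_time timestamps in seconds, \code{wake_time > bed_time}.
#' @param trim_h hours trimmed off each end.
#' @return List of class \code{sleep_period} with \code{bed_time},
#'   \code{wake_time}, \code{analysis_start}, \code{analysis_end},
#'   \code{usable}.
#' @export
sleep_period <- function(bed_time, wake_time, trim_h = 1) {
  if (wake_time <= bed_time) stop("wake_time must follow bed_time")
  a0 <- bed_time + trim_h * 3600
  a1 <- wake_time - trim_h * 3600
  structure(list(bed_time = bed_time, wake_time = wake_time,
                 analysis_start = a0, analysis_end = a1,
                 usable = a1 > a0),
            class = "sleep_period")
}

#' @export
print.sleep_period <- function(x, ...) {
  cat(sprintf("<sleep_period> bed %s  wake %s  analysis %s-%s%s\n",
              fmt_hm(x$bed_time), fmt_hm(x$wake_time),
              fmt_hm(x$analysis_start), fmt_hm(x$analysis_end),
              if (x$usable) "" else "  (unusable after trimming)"))
  invisible(x)
}

#' Estimate one night's sleep period from wearable streams
#'
#' Automated stand-in for manual bed/wake labelling: a second is a candidate
#' sleep second when (a) the 10-minute rolling median of accelerometer
#' magnitude lies in the lower part of its daily range — below
#' \code{q10 + activity_rel x (q90 - q10)} of the smoothed magnitudes, a
#' threshold that separates the night and day modes regardless of how much
#' of the record is sleep — (b) the rolling 10-minute step count is zero,
#' and (c) the rolling median heart rate is below the midpoint of its own
#' q10-q90 range (nocturnal bradycardia). The longest contiguous candidate
#' block of at least \code{min_sleep_h} hours is the sleep period; interior
#' interruptions up to \code{max_gap_min} minutes (posture shifts, brief
#' awakenings, bathroom bouts) are bridged first. Deterministic.
#'
#' @param hr data.frame \code{time_s}, \code{hr_bpm} at 1 Hz.
#' @param accel data.frame \code{time_s}, \code{magnitude} at 1 Hz.
#' @param steps data.frame \code{time_s}, \code{steps} (counts per second).
#' @param activity_rel accelerometer threshold position within the smoothed
#'   q10-q90 range, default 0.25.
#' @param hr_rel heart-rate threshold position within its q10-q90 range,
#'   default 0.5.
#' @param smooth_min rolling-median width in minutes, default 10.
#' @param max_gap_min longest interruption bridged inside a sleep block,
#'   default 30.
#' @param min_sleep_h minimum accepted block length in hours, default 3.
#' @param trim_h transition trim passed to [sleep_period()].
#' @return A [sleep_period()].
#' @export
estimate_sleep_period <- function(hr, accel, steps,
                                  activity_rel = 0.25, hr_rel = 0.5,
                                  smooth_min = 10, max_gap_min = 30,
                                  min_sleep_h = 3, trim_h = 1) {
  for (nm in c("hr", "accel", "steps")) {
    df <- get(nm)
    if (!is.data.frame(df) || !"time_s" %in% names(df)) {
      stop(sprintf("'%s' must be a data.frame with a time_s column", nm))
    }
  }
  span_h <- (max(hr$time_s) - min(hr$time_s)) / 3600
  if (span_h < 12) stop("streams must cover at least 12 h around the night")

  k <- smooth_min * 60
  hr_s <- roll_med(hr$hr_bpm, k)
  ac_s <- roll_med(accel$magnitude, k)
  # rolling step count over the same horizon, aligned to the HR clock
  st <- steps$steps[match(round(hr$time_s), round(steps$time_s))]
  st[is.na(st)] <- 0
  cs <- cumsum(st)
  half <- k %/% 2
  n <- length(st)
  st_s <- cs[pmin(n, seq_len(n) + half)] - cs[pmax(1L, seq_len(n) - half)] + st[pmax(1L, seq_len(n) - half)]

  range_thr <- function(x, rel) {
    q <- stats::quantile(x, c(0.10, 0.90), names = FALSE)
    q[1] + rel * (q[2] - q[1])
  }
  quiet <- ac_s < range_thr(ac_s, activity_rel) &
    st_s == 0 & hr_s < range_thr(hr_s, hr_rel)

  # bridge interruptions shorter than max_gap_min so one restless minute
  # does not split the night
  r <- rle(quiet)
  gap <- !r$values & r$lengths <= max_gap_min * 60
  inner <- which(gap)
  inner <- inner[inner > 1L & inner < length(r$values)]
  r$values[inner] <- TRUE
  quiet <- inverse.rle(r)

  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= min_sleep_h * 3600
  if (!any(ok)) {
    stop(sprintf("no resting block of at least %g h found in the night", min_sleep_h))
  }
  best <- which(ok)[which.max(r$lengths[ok])]
  sleep_period(hr$time_s[starts[best]], hr$time_s[ends[best]], trim_h = trim_h)
}

#' Normative reference table for HRV metrics
#'
#' Strata keyed by sex, age band and hour-of-day band give a reference mean
#' and SD per metric; [normative_transform()] turns a raw windowed metric
#' into a dimensionless z-value against its stratum. Published norms are not
#' bundled: the table is an input. [identity_normative_table()] (mean 0,
#' SD 1 everywhere) leaves values unchanged, and
#' [build_normative_table()] derives one from a reference cohort's own
#' windows.
#'
#' @param df data.frame with columns \code{sex}, \code{age_lo}, \code{age_hi},
#'   \code{hour_lo}, \code{hour_hi}, \code{metric}, \code{mean}, \code{sd}.
#'   Age bands are half-open \code{[age_lo, age_hi)}; hour bands inclusive
#'   \code{hour_lo..hour_hi}.
#' @return The validated table, classed \code{normative_table}.
#' @export
normative_table <- function(df) {
  need <- c("sex", "age_lo", "age_hi", "hour_lo", "hour_hi", "metric", "mean", "sd")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("normative table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$sd <= 0)) stop("normative reference SDs must be positive")
  structure(as.data.frame(df), class = c("normative_table", "data.frame"))
}

#' @rdname normative_table
#' @param metrics metric names covered by the identity table.
#' @param age_range ages covered.
#' @export
identity_normative_table <- function(metrics = c("sd1", "sd2", "sdnn"),
                                     age_range = c(18, 90)) {
  grid <- expand.grid(sex = c("F", "M"), metric = metrics,
                      stringsAsFactors = FALSE)
  normative_table(data.frame(sex = grid$sex, age_lo = age_range[1],
                             age_hi = age_range[2], hour_lo = 0, hour_hi = 23,
                             metric = grid$metric, mean = 0, sd = 1))
}

#' @rdname normative_table
#' @param windows kept \code{hrv_windows} rows pooled over a reference cohort,
#'   with added columns \code{sex}, \code{age}, \code{hour}.
#' @param age_breaks,hour_breaks band edges (left-closed) for stratification.
#' @export
build_normative_table <- function(windows,
                                  age_breaks = c(18, 40, 65, 90),
                                  hour_breaks = c(0, 6, 12, 18, 24)) {
  need <- c("sex", "age", "hour", "sd1", "sd2", "sdnn")
  miss <- setdiff(need, names(windows))
  if (length(miss)) stop("reference windows lack column(s): ", paste(miss, collapse = ", "))
  ab <- cut(windows$age, age_breaks, right = FALSE, labels = FALSE)
  hb <- cut(windows$hour, hour_breaks, right = FALSE, labels = FALSE)
  rows <- list()
  for (m in c("sd1", "sd2", "sdnn")) {
    agg <- stats::aggregate(windows[[m]],
                            by = list(sex = windows$sex, ab = ab, hb = hb),
                            FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                                sd = stats::sd(v, na.rm = TRUE)))
    rows[[m]] <- data.frame(sex = agg$sex,
                            age_lo = age_breaks[agg$ab],
                            age_hi = age_breaks[agg$ab + 1L],
                            hour_lo = hour_breaks[agg$hb],
                            hour_hi = hour_breaks[agg$hb + 1L] - 1L,
                            metric = m,
                            mean = agg$x[, "mean"], sd = agg$x[, "sd"])
  }
  out <- do.call(rbind, rows)
  out <- out[is.finite(out$sd) & out$sd > 0, ]
  rownames(out) <- NULL
  normative_table(out)
}

#' Transform a raw HRV value against its normative stratum
#'
#' @param value raw metric value (ms).
#' @param metric one of \code{"sd1"}, \code{"sd2"}, \code{"sdnn"}.
#' @param sex \code{"F"} or \code{"M"}.
#' @param age years.
#' @param hour hour of day, 0-23.
#' @param table a [normative_table()].
#' @return \code{(value - reference mean) / reference SD}, dimensionless.
#' @export
normative_transform <- function(value, metric, sex, age, hour, table) {
  if (!inherits(table, "normative_table")) stop("'table' must be a normative_table")
  hit <- table$metric == metric & table$sex == sex &
    table$age_lo <= age & age < table$age_hi &
    table$hour_lo <= hour & hour <= table$hour_hi
  if (!any(hit)) {
    stop(sprintf("no normative stratum for (sex=%s, age=%g, hour=%g, metric=%s)",
                 sex, age, hour, metric))
  }
  row <- table[which(hit)[1L], ]
  (value - row$mean) / row$sd
}
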