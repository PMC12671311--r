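#' Binarize static clinical covariates
#'
#' Transforms the disability and autonomic-dysfunction scores into binary
#' severity flags at the conventional cutoffs — EDSS 3, MSSS 3, ARMSS 4,
#' COMPASS 17 — using strict \code{>} (the scales define "light to no
#' disability" as at-or-below the cutoff). Scores of control participants
#' are set to 0 before the rule is applied.
#'
#' @param profiles participant data.frame with columns \code{group},
#'   \code{edss}, \code{msss}, \code{armss}, \code{compass}.
#' @param cutoffs named numeric cutoffs, defaults \code{c(edss = 3,
#'   msss = 3, armss = 4, compass = 17)}.
#' @return \code{profiles} with added logical columns \code{edss_severe},
#'   \code{msss_severe}, \code{armss_severe}, \code{ans_dysfunction}.
#' @export
#' @examples
#' p <- data.frame(group = c("MS", "control"), edss = c(3.5, 4),
#'                 msss = c(2, 9), armss = c(5, 0), compass = c(18, 30))
#' binarize_static(p)[, c("edss_severe", "ans_dysfunction")]
binarize_static <- function(profiles,
                            cutoffs = c(edss = 3, msss = 3, armss = 4, compass = 17)) {
  need <- c("group", "edss", "msss", "armss", "compass")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) stop("profiles lack column(s): ", paste(miss, collapse = ", "))
  sc <- profiles[, c("edss", "msss", "armss", "compass")]
  if (any(as.matrix(sc) < 0, na.rm = TRUE)) stop("scores must be non-negative")
  ctrl <- profiles$group != "MS"
  sc[ctrl, ] <- 0
  profiles$edss_severe <- sc$edss > cutoffs[["edss"]]
  profiles$msss_severe <- sc$msss > cutoffs[["msss"]]
  profiles$armss_severe <- sc$armss > cutoffs[["armss"]]
  profiles$ans_dysfunction <- sc$compass > cutoffs[["compass"]]
  profiles
}

#' Aggregate one day-state's window values
#'
#' The five per-variable aggregates of the daily feature scheme: minimum,
#' mean, maximum, minimum/mean ratio and maximum/mean ratio.
#'
#' @param values numeric window values of one variable within one day-state.
#' @return Named numeric \code{c(minimum, mean, maximum, minimum_ratio,
#'   maximum_ratio)}; all \code{NA} when no value is available (an empty
#'   state is reported as explicitly missing, never as zero).
#' @export
#' @examples
#' aggregate_day(c(50, 100, 150))
aggregate_day <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) {
    return(c(minimum = NA_real_, mean = NA_real_, maximum = NA_real_,
             minimum_ratio = NA_real_, maximum_ratio = NA_real_))
  }
  m <- mean(values)
  c(minimum = min(values), mean = m, maximum = max(values),
    minimum_ratio = min(values) / m, maximum_ratio = max(values) / m)
}

#' Mean of a day's stress logs
#'
#' @param stress numeric logs on the 1-10 scale recorded within the day.
#' @return Arithmetic mean, or \code{NA} when no log exists.
#' @export
aggregate_stress <- function(stress) {
  stress <- stress[!is.na(stress)]
  if (any(stress < 1 | stress > 10)) stop("stress values must lie in 1..10")
  if (!length(stress)) return(NA_real_)
  mean(stress)
}

#' Assign HRV windows to wake-anchored days and awake/asleep states
#'
#' A "day" runs from one wake-up to the next. Within day \code{d}, a window
#' is \code{asleep} when fully inside the trimmed analysis bounds of night
#' \code{d}, \code{awake} when fully inside \code{[wake_d, bed_d]}, and
#' \code{trimmed} (assigned to neither state) when it touches the 1-hour
#' transition zones after going to bed or before waking.
#'
#' @param windows an \code{hrv_windows} data.frame ([window_series()]).
#' @param periods list of [sleep_period()]s, one per night, in order; night
#'   \code{d} ends day \code{d}.
#' @param day_starts numeric wake times opening each day (same length as
#'   \code{periods}; day \code{d} spans \code{day_starts[d]} to
#'   \code{periods[[d]]$wake_time}).
#' @return \code{windows} with added integer \code{day} (NA outside any day)
#'   and character \code{state} in \code{"awake"}, \code{"asleep"},
#'   \code{"trimmed"}.
#' @export
split_day <- function(windows, periods, day_starts) {
  if (length(periods) != length(day_starts)) {
    stop("'periods' and 'day_starts' must align (one night per day)")
  }
  bed <- vapply(periods, `[[`, 0, "bed_time")
  wake <- vapply(periods, `[[`, 0, "wake_time")
  a0 <- vapply(periods, `[[`, 0, "analysis_start")
  a1 <- vapply(periods, `[[`, 0, "analysis_end")
  if (length(bed) > 1 && any(bed[-1] < wake[-length(wake)])) {
    stop("overlapping sleep periods")
  }
  n <- nrow(windows)
  day <- rep(NA_integer_, n)
  state <- rep(NA_character_, n)
  for (d in seq_along(periods)) {
    in_day <- windows$start >= day_starts[d] & windows$end <= wake[d]
    asleep <- in_day & windows$start >= a0[d] & windows$end <= a1[d]
    awake <- in_day & windows$end <= bed[d]
    trimmed <- in_day & !asleep & !awake
    day[in_day] <- d
    state[asleep] <- "asleep"
    state[awake] <- "awake"
    state[trimmed] <- "trimmed"
  }
  windows$day <- day
  windows$state <- state
  windows
}

mean_in <- function(df, col, t0, t1) {
  sel <- df$time_s >= t0 & df$time_s <= t1
  if (!any(sel)) return(NA_real_)
  mean(df[[col]][sel])
}

sum_in <- function(df, col, t0, t1) {
  sel <- df$time_s >= t0 & df$time_s <= t1
  sum(df[[col]][sel])
}

#' Build the per-participant-day feature table from a stream cohort
#'
#' Runs the full signal chain for every participant: IBI cleaning and
#' 5-minute Poincare windows, automated sleep-period estimation (or the
#' cohort's true bed/wake times when \code{use_truth_periods = TRUE}),
#' transition trimming, the resting-HR eligibility filter, wake-anchored day
#' splitting, and the min/mean/max/ratio aggregation per variable and state,
#' joined with diary variables and binarized static covariates.
#'
#' @param cohort an \code{slq_cohort} from [simulate_cohort()] or an
#'   equivalent list read by [read_cohort_csv()].
#' @param use_truth_periods use the generator's true bed/wake times instead
#'   of [estimate_sleep_period()] (faster; exercises the downstream stages
#'   against exact segmentation).
#' @param resting_sleep apply the resting-HR filter to sleep windows as well
#'   as daytime windows (default TRUE).
#' @param normative optional [normative_table()]; when supplied, windowed
#'   HRV metrics are transformed to normative z-values before aggregation.
#' @param min_state_windows minimum kept windows per day-state before the
#'   state's aggregates are reported (default 1).
#' @param detector [artifact_params()] settings for the cleaning stage.
#' @return data.frame, one row per participant-day, with columns named
#'   \code{<stat>_<var>_<state>} / \code{<var>_<minimum|maximum>_ratio_<state>}
#'   plus \code{sleep_duration}, \code{awake_duration}, \code{motion_*},
#'   \code{steps_*}, diary and static columns.
#' @export
build_daily_features <- function(cohort, use_truth_periods = FALSE,
                                 resting_sleep = TRUE, normative = NULL,
                                 min_state_windows = 1L,
                                 detector = artifact_params()) {
  profiles <- binarize_static(cohort$participants)
  out <- list()
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    st <- cohort$streams[[p$id]]
    win <- compute_hrv_windows(st$ibi, params = detector)
    nd <- max(cohort$diary$day[cohort$diary$participant == p$id])
    truth_p <- cohort$truth$bed_wake[cohort$truth$bed_wake$participant == p$id, ]

    periods <- vector("list", nd)
    day_starts <- numeric(nd)
    prev_wake <- min(st$hr$time_s)
    for (d in seq_len(nd)) {
      if (use_truth_periods) {
        periods[[d]] <- sleep_period(truth_p$bed_time[d], truth_p$wake_time[d])
      } else {
        sel <- function(df) df[df$time_s >= prev_wake - 3600 &
                                 df$time_s <= (d) * 86400 + 12 * 3600, ]
        periods[[d]] <- tryCatch(
          estimate_sleep_period(sel(st$hr), sel(st$accel), sel(st$steps)),
          error = function(e) sleep_period(truth_p$bed_time[d], truth_p$wake_time[d]))
      }
      day_starts[d] <- prev_wake
      prev_wake <- periods[[d]]$wake_time
    }

    win <- split_day(win, periods, day_starts)
    thr_ok <- classify_resting(win$mean_hr, age = p$age)
    if (!resting_sleep) thr_ok[win$state == "asleep"] <- TRUE
    win$resting <- !is.na(win$mean_hr) & thr_ok

    if (!is.null(normative)) {
      hr_mid <- floor(((win$start + win$end) / 2) %% 86400 / 3600)
      for (m in c("sd1", "sd2", "sdnn")) {
        win[[m]] <- vapply(seq_len(nrow(win)), function(j) {
          if (is.na(win[[m]][j])) return(NA_real_)
          normative_transform(win[[m]][j], m, p$sex, p$age, hr_mid[j], normative)
        }, 0)
      }
    }

    diary_p <- cohort$diary[cohort$diary$participant == p$id, ]
    for (d in seq_len(nd)) {
      per <- periods[[d]]
      row <- list(participant = p$id, day = d)
      for (state in c("awake", "asleep")) {
        use <- !is.na(win$day) & win$day == d & win$state == state &
          win$kept & win$resting
        for (v in c("mean_hr", "sd1", "sd2", "sdnn")) {
          vn <- if (v == "mean_hr") "hr" else v
          agg <- if (sum(use) >= min_state_windows) aggregate_day(win[[v]][use]) else
            aggregate_day(numeric(0))
          row[[paste0("minimum_", vn, "_", state)]] <- agg[["minimum"]]
          row[[paste0("mean_", vn, "_", state)]] <- agg[["mean"]]
          row[[paste0("maximum_", vn, "_", state)]] <- agg[["maximum"]]
          row[[paste0(vn, "_minimum_ratio_", state)]] <- agg[["minimum_ratio"]]
          row[[paste0(vn, "_maximum_ratio_", state)]] <- agg[["maximum_ratio"]]
        }
      }
      row$motion_asleep <- mean_in(st$accel, "magnitude", per$analysis_start, per$analysis_end)
      row$motion_awake <- mean_in(st$accel, "magnitude", day_starts[d], per$bed_time)
      row$steps_asleep <- sum_in(st$steps, "steps", per$analysis_start, per$analysis_end)
      row$steps_awake <- sum_in(st$steps, "steps", day_starts[d], per$bed_time)
      row$sleep_duration <- (per$wake_time - per$bed_time) / 3600
      row$awake_duration <- (per$bed_time - day_starts[d]) / 3600
      stress_d <- cohort$stress[cohort$stress$participant == p$id &
                                  cohort$stress$time_s >= day_starts[d] &
                                  cohort$stress$time_s <= per$bed_time, ]
      row$mean_stress_awake <- aggregate_stress(stress_d$stress)
      dr <- diary_p[diary_p$day == d, ]
      row$awake_at_night <- if (nrow(dr)) as.numeric(dr$awake_at_night[1]) else NA_real_
      row$sleep_medication <- if (nrow(dr)) as.numeric(dr$sleep_medication[1]) else NA_real_
      row$sleep_quality <- if (nrow(dr)) dr$sleep_quality[1] else NA_integer_
      for (cl in c("age", "sex", "group", "edss_severe", "msss_severe",
                   "armss_severe", "ans_dysfunction", "spinal_cord")) {
        row[[cl]] <- p[[cl]]
      }
      out[[length(out) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
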