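#' Configuration of the synthetic cohort generator
#'
#' Collects every knob of the ground-truth generator: cohort composition,
#' circadian heart-rate structure, night-time HRV gain, beat-level artifact
#' rate, diary behaviour, and the logistic effect vector that produces the
#' sleep-quality responses. Defaults emulate a two-week wearable study of a
#' mixed cohort of people with multiple sclerosis and healthy controls.
#'
#' @param n_participants cohort size (>= 2). Default 60.
#' @param n_days study days per participant (>= 2). Default 14.
#' @param fraction_ms proportion of participants in the MS group. Default
#'   0.69 (53 of 77 in the emulated study design).
#' @param age_range inclusive age bounds, years.
#' @param sex_ratio proportion of female participants.
#' @param bed_time_mean,bed_time_sd going-to-bed clock time, seconds after
#'   midnight, and its night-to-night SD (seconds). Default 23:00 +/- 30 min.
#' @param wake_time_mean,wake_time_sd wake-up clock time and SD. Default
#'   07:00 +/- 30 min.
#' @param hr_day_mean population daytime heart-rate level, bpm.
#' @param hr_night_dip nocturnal bradycardia depth, bpm below the daytime
#'   level. Default 12.
#' @param hrv_night_gain multiplicative nocturnal gain on beat-to-beat
#'   variability (> 1 gives the elevated night HRV the analysis expects).
#' @param ibi_sd_ms marginal daytime SD of the interbeat intervals, ms.
#' @param ar_phi lag-1 autocorrelation of the beat-to-beat process; splits
#'   variability between the short-term (SD1) and long-term (SD2) axes.
#' @param artifact_rate per-beat probability of an injected artifact
#'   (missed beat or ectopic split), in [0, 0.5). Default 0.005, a typical
#'   artifact incidence for a well-seated optical wearable; the window
#'   exclusion rule then discards a realistic minority of windows.
#' @param stress_mean_range per-participant habitual stress level bounds on
#'   the 1-10 scale.
#' @param stress_day_sd day-to-day SD of the daily stress level.
#' @param awake_night_prob per-night probability of a reported nocturnal
#'   awakening (with a matching wake bout in the streams).
#' @param bathroom_prob per-night probability of a brief step bout during
#'   sleep.
#' @param effect_vector named numeric: logistic coefficients (log-odds per 1
#'   within-participant SD) applied to the normalized daily features shared
#'   by both groups.
#' @param ms_effect_vector named numeric: additional coefficients applied in
#'   the MS group only.
#' @param noise_sd scale of the latent logistic noise on the sleep-quality
#'   score; 1 gives coefficients directly on the log-odds scale.
#' @param seed RNG seed; every simulation is a deterministic function of the
#'   config including this seed.
#' @return A validated list of class \code{sim_config}.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 4, n_days = 3, seed = 7)
#' cfg$n_days
sim_config <- function(n_participants = 60L,
                       n_days = 14L,
                       fraction_ms = 0.69,
                       age_range = c(18, 70),
                       sex_ratio = 0.62,
                       bed_time_mean = 23 * 3600, bed_time_sd = 30 * 60,
                       wake_time_mean = 7 * 3600, wake_time_sd = 30 * 60,
                       hr_day_mean = 75, hr_night_dip = 12,
                       hrv_night_gain = 1.5,
                       ibi_sd_ms = 30, ar_phi = 0.8,
                       artifact_rate = 0.005,
                       stress_mean_range = c(2, 6), stress_day_sd = 1.2,
                       awake_night_prob = 0.3,
                       bathroom_prob = 0.3,
                       effect_vector = c(sleep_duration = 0.5,
                                         awake_at_night = -0.6,
                                         mean_stress_awake = -0.45,
                                         mean_sd1_asleep = 0.45,
                                         motion_asleep = -0.4,
                                         maximum_sdnn_asleep = 0.3),
                       ms_effect_vector = c(minimum_hr_asleep = 0.6),
                       noise_sd = 1,
                       seed = 1L) {
  n_participants <- as.integer(n_participants)
  n_days <- as.integer(n_days)
  if (n_participants < 2L) stop("'n_participants' must be >= 2")
  if (n_days < 2L) stop("'n_days' must be >= 2")
  stopifnot_scalar(fraction_ms, "fraction_ms", 0, 1)
  stopifnot_scalar(sex_ratio, "sex_ratio", 0, 1)
  stopifnot_scalar(artifact_rate, "artifact_rate", 0, 0.5, strict_hi = TRUE)
  stopifnot_scalar(awake_night_prob, "awake_night_prob", 0, 1)
  stopifnot_scalar(bathroom_prob, "bathroom_prob", 0, 1)
  stopifnot_scalar(hrv_night_gain, "hrv_night_gain", 0, Inf, strict_lo = TRUE)
  stopifnot_scalar(ar_phi, "ar_phi", 0, 1, strict_hi = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", 0, Inf, strict_lo = TRUE)
  stopifnot_scalar(hr_night_dip, "hr_night_dip", 0, hr_day_mean - 30)
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stop("'age_range' must be increasing bounds")
  }
  if (length(effect_vector) && is.null(names(effect_vector))) {
    stop("'effect_vector' must be named by feature")
  }
  structure(list(n_participants = n_participants, n_days = n_days,
                 fraction_ms = fraction_ms, age_range = age_range,
                 sex_ratio = sex_ratio,
                 bed_time_mean = bed_time_mean, bed_time_sd = bed_time_sd,
                 wake_time_mean = wake_time_mean, wake_time_sd = wake_time_sd,
                 hr_day_mean = hr_day_mean, hr_night_dip = hr_night_dip,
                 hrv_night_gain = hrv_night_gain, ibi_sd_ms = ibi_sd_ms,
                 ar_phi = ar_phi, artifact_rate = artifact_rate,
                 stress_mean_range = stress_mean_range,
                 stress_day_sd = stress_day_sd,
                 awake_night_prob = awake_night_prob,
                 bathroom_prob = bathroom_prob,
                 effect_vector = effect_vector,
                 ms_effect_vector = ms_effect_vector,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# participant table shared by both generator levels
simulate_participants <- function(config) {
  n <- config$n_participants
  n_ms <- round(config$fraction_ms * n)
  group <- sample(rep(c("MS", "control"), c(n_ms, n - n_ms)))
  age <- round(stats::runif(n, config$age_range[1], config$age_range[2]))
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
  is_ms <- group == "MS"
  ms_type <- ifelse(!is_ms, "none",
                    ifelse(stats::runif(n) < 0.17, "PMS", "RRMS"))
  edss <- ifelse(is_ms, round(pmin(8, stats::rgamma(n, 2, 0.8)) * 2) / 2, 0)
  msss <- ifelse(is_ms, round(pmin(10, stats::rgamma(n, 2, 0.7)), 1), 0)
  armss <- ifelse(is_ms, round(pmin(10, stats::rgamma(n, 2.2, 0.6)), 1), 0)
  # controls get a recorded questionnaire score too; the analysis zeroes it
  compass <- round(ifelse(is_ms, pmin(60, stats::rgamma(n, 2, 0.12)),
                          stats::runif(n, 0, 20)), 1)
  spinal <- is_ms & stats::runif(n) < 0.45
  data.frame(id = sprintf("P%02d", seq_len(n)), age = age, sex = sex,
             group = group, ms_type = ms_type, edss = edss, msss = msss,
             armss = armss, compass = compass, spinal_cord = spinal,
             stringsAsFactors = FALSE)
}

# AR(1) noise with marginal SD `sd_marg`, vectorised
ar1_noise <- function(n, phi, sd_marg) {
  innov <- stats::rnorm(n, 0, sd_marg * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# smooth circadian HR curve: day plateau `hr_day`, sleep plateau
# `hr_day - dip`, 30-min cosine ramps at bed and wake
circadian_hr <- function(t, bed, wake, hr_day, dip, ramp = 1800) {
  bed <- rep_len(bed, length(t))
  wake <- rep_len(wake, length(t))
  frac <- rep(0, length(t))
  frac[t >= bed + ramp & t <= wake - ramp] <- 1
  r1 <- t > bed & t < bed + ramp
  frac[r1] <- (1 - cos(pi * (t[r1] - bed[r1]) / ramp)) / 2
  r2 <- t > wake - ramp & t < wake
  frac[r2] <- (1 + cos(pi * (t[r2] - (wake[r2] - ramp)) / ramp)) / 2
  hr_day - dip * frac
}

#' Simulate a full wearable cohort with ground truth
#'
#' Generates, per participant, continuous beat-level interbeat intervals,
#' 1 Hz heart rate and accelerometer magnitude, per-second step counts,
#' stress logs and morning sleep-quality diaries over \code{n_days} days,
#' together with a truth record (bed/wake times, artifact positions,
#' per-night latent features, the effect vector, and the latent labels).
#'
#' Heart rate follows a smooth circadian curve with nocturnal bradycardia;
#' interbeat intervals are an AR(1)-modulated Gaussian around
#' \code{60000 / HR(t)} ms whose marginal SD is multiplied by
#' \code{hrv_night_gain} during true sleep, so nocturnal SD1 exceeds diurnal
#' SD1 in expectation. Artifacts are injected as missed beats (two intervals
#' merged) and ectopic splits (one interval divided), the two classes
#' beat-editing detectors target. Step counts are zero during true sleep
#' apart from optional brief bathroom bouts.
#'
#' Beat-level simulation costs about 10^5 beats per participant-day; use
#' this generator at small \code{n_participants}/\code{n_days} and
#' [simulate_feature_cohort()] for modelling-scale cohorts.
#'
#' @param config a [sim_config()].
#' @return List of class \code{slq_cohort}: \code{participants},
#'   \code{streams} (per participant: \code{ibi}, \code{hr}, \code{accel},
#'   \code{steps} data.frames), \code{stress}, \code{diary}, \code{truth},
#'   \code{config}.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  with_seed(config$seed, {
    participants <- simulate_participants(config)
    streams <- list()
    stress_logs <- list()
    truth_bw <- list()
    truth_art <- list()
    truth_feat <- list()
    for (i in seq_len(nrow(participants))) {
      p <- participants[i, ]
      sim <- simulate_participant_streams(p, config)
      streams[[p$id]] <- sim$streams
      stress_logs[[i]] <- sim$stress
      truth_bw[[i]] <- sim$bed_wake
      truth_art[[i]] <- sim$artifacts
      truth_feat[[i]] <- sim$features
    }
    features <- do.call(rbind, truth_feat)
    resp <- simulate_cohort_responses(features, participants, config)
    diary <- data.frame(participant = features$participant,
                        day = features$day,
                        sleep_quality = resp$sleep_quality,
                        awake_at_night = features$awake_at_night == 1,
                        sleep_medication = features$sleep_medication == 1)
    structure(list(participants = participants,
                   streams = streams,
                   stress = do.call(rbind, stress_logs),
                   diary = diary,
                   truth = list(bed_wake = do.call(rbind, truth_bw),
                                artifacts = do.call(rbind, truth_art),
                                features = features,
                                labels = resp,
                                effect_vector = config$effect_vector,
                                ms_effect_vector = config$ms_effect_vector),
                   config = config),
              class = "slq_cohort")
  })
}

# one participant's continuous streams over config$n_days nights
simulate_participant_streams <- function(p, config) {
  nd <- config$n_days
  day_s <- 86400
  hr_day_p <- config$hr_day_mean + stats::rnorm(1, 0, 4)
  med_flag <- stats::runif(1) < 0.15

  wake <- vapply(0:nd, function(d) {
    d * day_s + stats::rnorm(1, config$wake_time_mean, config$wake_time_sd)
  }, 0)
  bed <- vapply(seq_len(nd), function(d) {
    (d - 1) * day_s + stats::rnorm(1, config$bed_time_mean, config$bed_time_sd)
  }, 0)
  # keep nights well-formed: bed on evening d, wake on morning d+1
  bed <- pmin(pmax(bed, wake[1:nd] + 6 * 3600), wake[2:(nd + 1)] - 4 * 3600)

  # per-night latent drivers (these are the ground-truth features)
  dip_n <- pmax(4, config$hr_night_dip + stats::rnorm(nd, 0, 2))
  hrv_scale_n <- config$ibi_sd_ms * config$hrv_night_gain * exp(stats::rnorm(nd, 0, 0.15))
  motion_n <- exp(stats::rnorm(nd, log(8), 0.3))
  awake_night <- stats::runif(nd) < config$awake_night_prob
  stress_day <- pmin(10, pmax(1, stats::runif(1, config$stress_mean_range[1],
                                              config$stress_mean_range[2]) +
                                stats::rnorm(nd, 0, config$stress_day_sd)))

  t_end <- wake[nd + 1] + 3600
  tt <- seq(0, ceiling(t_end))
  night_of <- function(t) findInterval(t, bed)  # 0 before first bed
  in_sleep <- function(t) {
    nb <- night_of(t)
    nb >= 1 & nb <= nd & t < wake[pmin(nb, nd) + 1]
  }
  nb_tt <- pmax(1L, pmin(night_of(tt), nd))
  hr_curve <- hr_day_p
  hr_curve <- circadian_hr(tt, bed[nb_tt], wake[nb_tt + 1L], hr_day_p, dip_n[nb_tt])
  hr_curve[tt < bed[1]] <- hr_day_p  # before first night
  sleeping <- in_sleep(tt)

  # nocturnal awakenings: 15-min bout mid-night raises HR/motion
  bout_mask <- rep(FALSE, length(tt))
  for (d in which(awake_night)) {
    mid <- stats::runif(1, bed[d] + 7200, wake[d + 1] - 7200)
    bout_mask[tt >= mid & tt < mid + 900] <- TRUE
  }
  hr_curve[bout_mask] <- hr_curve[bout_mask] + 12
  hr_slow <- 2 * sin(2 * pi * tt / 5400 + stats::runif(1, 0, 2 * pi))
  hr_stream <- data.frame(time_s = tt,
                          hr_bpm = hr_curve + hr_slow + stats::rnorm(length(tt), 0, 1.5))

  # accelerometer magnitude (arbitrary milli-g units)
  mag <- numeric(length(tt))
  awk <- !sleeping
  mag[awk] <- pmax(0, 60 + 20 * sin(2 * pi * tt[awk] / 3600) +
                     stats::rnorm(sum(awk), 0, 18))
  mag[sleeping] <- motion_n[nb_tt[sleeping]] + abs(stats::rnorm(sum(sleeping), 0, 2))
  mag[bout_mask] <- mag[bout_mask] + 50
  accel <- data.frame(time_s = tt, magnitude = mag)

  # steps: intermittent while awake, zero asleep except bathroom bouts
  st <- integer(length(tt))
  st[awk] <- stats::rbinom(sum(awk), 2, 0.05)
  for (d in seq_len(nd)) {
    if (stats::runif(1) < config$bathroom_prob) {
      b0 <- stats::runif(1, bed[d] + 5400, wake[d + 1] - 5400)
      sel <- tt >= b0 & tt < b0 + 150
      st[sel] <- stats::rbinom(sum(sel), 2, 0.4)
      mag[sel] <- mag[sel] + 40
    }
  }
  steps <- data.frame(time_s = tt, steps = st)
  accel$magnitude <- mag

  ibi <- simulate_ibi_stream(tt, hr_curve, sleeping, hrv_scale_n, nb_tt, config)
  if (nrow(ibi$artifacts)) ibi$artifacts$participant <- p$id

  stress <- do.call(rbind, lapply(seq_len(nd), function(d) {
    k <- 3L
    at <- sort(stats::runif(k, wake[d] + 1800, bed[d] - 1800))
    data.frame(participant = p$id, time_s = at,
               stress = pmin(10, pmax(1, round(stress_day[d] + stats::rnorm(k, 0, 0.8)))))
  }))

  feats <- data.frame(participant = p$id, day = seq_len(nd),
                      sleep_duration = (wake[2:(nd + 1)] - bed) / 3600,
                      awake_at_night = as.numeric(awake_night),
                      sleep_medication = as.numeric(med_flag),
                      mean_stress_awake = stress_day,
                      motion_asleep = motion_n,
                      minimum_hr_asleep = hr_day_p - dip_n,
                      mean_sd1_asleep = hrv_scale_n * sqrt(1 - config$ar_phi),
                      maximum_sdnn_asleep = hrv_scale_n)
  list(streams = list(ibi = ibi$series, hr = hr_stream, accel = accel,
                      steps = steps),
       stress = stress,
       bed_wake = data.frame(participant = p$id, day = seq_len(nd),
                             bed_time = bed, wake_time = wake[2:(nd + 1)]),
       artifacts = ibi$artifacts,
       features = feats)
}

# beat stream with AR(1) variability and injected artifacts
simulate_ibi_stream <- function(tt, hr_curve, sleeping, hrv_scale_n, nb_tt, config) {
  t0 <- tt[1]; t1 <- tt[length(tt)]
  mean_ibi_s <- 60 / mean(hr_curve)
  n_beats <- ceiling((t1 - t0) / mean_ibi_s) + 10L
  # provisional beat clock on the mean grid; HR varies slowly enough that
  # evaluating the curve at approximate beat times is exact to < 1 bpm
  t_approx <- pmin(t0 + (seq_len(n_beats) - 1L) * mean_ibi_s, t1)
  idx <- pmin(length(tt), floor(t_approx - t0) + 1L)
  base <- 60000 / hr_curve[idx]
  scale <- ifelse(sleeping[idx], hrv_scale_n[nb_tt[idx]], config$ibi_sd_ms)
  z <- ar1_noise(n_beats, config$ar_phi, 1) * scale
  ibi_ms <- pmax(300, base + z)
  times <- t0 + cumsum(ibi_ms) / 1000
  keep <- times <= t1
  ibi_ms <- ibi_ms[keep]; times <- times[keep]

  art <- data.frame(participant = character(0), time_s = numeric(0),
                    type = character(0))
  if (config$artifact_rate > 0) {
    n <- length(ibi_ms)
    cand <- which(stats::runif(n) < config$artifact_rate)
    cand <- cand[cand > 1L & cand < n - 1L]
    if (length(cand) > 1L) cand <- cand[c(TRUE, diff(cand) > 2L)]  # no overlap
    if (length(cand)) {
      missed <- stats::runif(length(cand)) < 0.5
      art <- data.frame(time_s = times[cand],
                        type = ifelse(missed, "missed", "ectopic"))
      # the beat clock is continuous, so both corruption classes are pure
      # edits of the beat-time set: a missed beat deletes a detection (its
      # two intervals fuse); an ectopic inserts a spurious one
      ect <- cand[!missed]
      u <- stats::runif(length(ect), 0.35, 0.65)
      extras <- times[ect] - (1 - u) * ibi_ms[ect] / 1000
      times <- sort(c(times[-cand[missed]], extras))
      ibi_ms <- c(ibi_ms[1L], diff(times) * 1000)
    }
  }
  good <- c(TRUE, diff(times) > 0)
  list(series = ibi_series(times[good], ibi_ms[good]),
       artifacts = art)
}

# truth features -> diary responses via the latent logistic model
simulate_cohort_responses <- function(features, participants, config) {
  keys <- union(names(config$effect_vector), names(config$ms_effect_vector))
  missing_keys <- setdiff(keys, names(features))
  if (length(missing_keys)) {
    stop("effect_vector names absent from the feature table: ",
         paste(missing_keys, collapse = ", "),
         "; valid names: ", paste(setdiff(names(features), c("participant", "day")),
                                  collapse = ", "))
  }
  norm <- scale_within(features, id = features$participant, cols = keys)
  is_ms <- participants$group[match(features$participant, participants$id)] == "MS"
  simulate_responses(norm, config$effect_vector,
                     noise_sd = config$noise_sd, seed = NULL,
                     group = is_ms,
                     group_effect_vector = config$ms_effect_vector)
}

# within-participant z-scoring used by the generator (truth side); the
# modelling module has its own provenance-tracking version
scale_within <- function(df, id, cols) {
  out <- df
  for (cl in cols) {
    mu <- stats::ave(df[[cl]], id, FUN = mean)
    sdv <- stats::ave(df[[cl]], id, FUN = stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    out[[cl]] <- (df[[cl]] - mu) / sdv
  }
  out
}

#' Draw sleep-quality responses from a known logistic effect vector
#'
#' The latent night score is the linear combination of the supplied
#' normalized features under \code{effect_vector} (plus
#' \code{group_effect_vector} for rows with \code{group = TRUE}) plus
#' logistic noise of scale \code{noise_sd}. The binary label is
#' \code{latent > 0} — i.e. labels follow a logistic regression model with
#' the stated coefficients — and the 1-5 morning rating is a monotone
#' discretization of the latent score centred near 3.7, so binarizing the
#' rating at the personal average approximately recovers the labels.
#'
#' @param features data.frame of (already normalized) features containing
#'   every name in the effect vectors.
#' @param effect_vector named coefficients on the normalized scale.
#' @param noise_sd logistic noise scale.
#' @param seed optional seed (NULL draws from the current RNG stream).
#' @param group optional logical vector marking rows that also receive
#'   \code{group_effect_vector}.
#' @param group_effect_vector optional named coefficients for flagged rows.
#' @return data.frame with \code{lin} (noise-free linear predictor),
#'   \code{latent}, \code{label} (1 = high-quality sleep),
#'   \code{sleep_quality} (integer 1-5).
#' @export
simulate_responses <- function(features, effect_vector, noise_sd = 1,
                               seed = NULL, group = NULL,
                               group_effect_vector = NULL) {
  keys <- names(effect_vector)
  bad <- setdiff(keys, names(features))
  if (length(bad)) {
    stop("unknown feature name(s): ", paste(bad, collapse = ", "),
         "; valid names: ",
         paste(setdiff(names(features), c("participant", "day")), collapse = ", "))
  }
  with_seed(seed, {
    n <- nrow(features)
    lin <- rep(0, n)
    for (k in keys) lin <- lin + effect_vector[[k]] * features[[k]]
    if (!is.null(group_effect_vector) && !is.null(group)) {
      gbad <- setdiff(names(group_effect_vector), names(features))
      if (length(gbad)) stop("unknown feature name(s): ", paste(gbad, collapse = ", "))
      gl <- rep(0, n)
      for (k in names(group_effect_vector)) {
        gl <- gl + group_effect_vector[[k]] * features[[k]]
      }
      lin <- lin + gl * as.numeric(group)
    }
    latent <- lin + stats::rlogis(n, 0, noise_sd)
    data.frame(lin = lin, latent = latent,
               label = as.integer(latent > 0),
               sleep_quality = pmin(5L, pmax(1L, as.integer(round(3.7 + 0.75 * latent)))))
  })
}

#' Simulate a daily feature table directly (modelling-scale cohorts)
#'
#' Draws the per-participant-day feature table the full pipeline would
#' produce, from the same marginal structure as [simulate_cohort()] but
#' without beat- or second-level streams, making cohorts of hundreds of
#' participant-days cheap. Each feature is participant mean + day-to-day
#' noise; responses come from [simulate_responses()] under the config's
#' effect vectors, so the table carries known ground truth for the
#' modelling and evaluation modules.
#'
#' @param config a [sim_config()].
#' @return List of class \code{slq_feature_cohort}: \code{participants},
#'   \code{features} (one row per participant-day incl. \code{sleep_quality}),
#'   \code{truth} (latent scores, labels, effect vectors).
#' @export
simulate_feature_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  with_seed(config$seed, {
    participants <- simulate_participants(config)
    n <- nrow(participants)
    nd <- config$n_days
    id <- rep(participants$id, each = nd)
    day <- rep(seq_len(nd), n)

    draw <- function(pop_mean, between_sd, within_sd, lo = -Inf, hi = Inf) {
      mu <- rep(stats::rnorm(n, pop_mean, between_sd), each = nd)
      pmin(hi, pmax(lo, mu + stats::rnorm(n * nd, 0, within_sd)))
    }
    phi <- config$ar_phi
    sd1_night <- config$ibi_sd_ms * config$hrv_night_gain * sqrt(1 - phi)
    sd1_day <- config$ibi_sd_ms * sqrt(1 - phi)
    feats <- data.frame(
      participant = id, day = day,
      sleep_duration = draw(7.3, 0.5, 0.9, lo = 3, hi = 12),
      awake_duration = draw(16.2, 0.5, 0.9, lo = 10, hi = 20),
      awake_at_night = as.numeric(stats::runif(n * nd) < config$awake_night_prob),
      sleep_medication = rep(as.numeric(stats::runif(n) < 0.15), each = nd),
      mean_stress_awake = draw(mean(config$stress_mean_range), 1.2,
                               config$stress_day_sd, lo = 1, hi = 10),
      motion_asleep = exp(draw(log(8), 0.25, 0.3)),
      minimum_hr_asleep = draw(config$hr_day_mean - config$hr_night_dip - 8,
                               4, 2.5, lo = 35),
      mean_hr_asleep = draw(config$hr_day_mean - config$hr_night_dip, 4, 2, lo = 40),
      mean_hr_awake = draw(config$hr_day_mean, 4, 2.5, lo = 45),
      hr_minimum_ratio_awake = draw(0.78, 0.03, 0.04, lo = 0.4, hi = 1),
      mean_sd1_asleep = exp(draw(log(sd1_night), 0.2, 0.18, lo = log(2))),
      maximum_sd1_asleep = exp(draw(log(2 * sd1_night), 0.2, 0.2, lo = log(3))),
      minimum_sd1_awake = exp(draw(log(0.5 * sd1_day), 0.2, 0.25)),
      mean_sd2_asleep = exp(draw(log(config$ibi_sd_ms * config$hrv_night_gain *
                                       sqrt(1 + phi)), 0.2, 0.18)),
      minimum_sd2_asleep = exp(draw(log(0.6 * config$ibi_sd_ms * sqrt(1 + phi)),
                                    0.2, 0.2)),
      maximum_sd2_asleep = exp(draw(log(2.2 * config$ibi_sd_ms * sqrt(1 + phi)),
                                    0.2, 0.2)),
      mean_sdnn_asleep = exp(draw(log(config$ibi_sd_ms * config$hrv_night_gain),
                                  0.2, 0.18)),
      maximum_sdnn_asleep = exp(draw(log(2 * config$ibi_sd_ms * config$hrv_night_gain),
                                     0.2, 0.2)),
      sdnn_maximum_ratio_asleep = draw(2.0, 0.15, 0.25, lo = 1),
      steps_awake = round(exp(draw(log(7000), 0.3, 0.35, lo = log(200)))),
      stringsAsFactors = FALSE)

    keys <- union(names(config$effect_vector), names(config$ms_effect_vector))
    norm <- scale_within(feats, id = feats$participant, cols = keys)
    is_ms <- participants$group[match(feats$participant, participants$id)] == "MS"
    resp <- simulate_responses(norm, config$effect_vector,
                               noise_sd = config$noise_sd, seed = NULL,
                               group = is_ms,
                               group_effect_vector = config$ms_effect_vector)
    feats$sleep_quality <- resp$sleep_quality
    structure(list(participants = participants, features = feats,
                   truth = list(lin = resp$lin,
                                latent = resp$latent, label = resp$label,
                                effect_vector = config$effect_vector,
                                ms_effect_vector = config$ms_effect_vector),
                   config = config),
              class = "slq_feature_cohort")
  })
}

#' @export
print.slq_cohort <- function(x, ...) {
  cat(sprintf("<slq_cohort> %d participants x %d days (stream-level, seed %d)\n",
              nrow(x$participants), x$config$n_days, x$config$seed))
  invisible(x)
}

#' @export
print.slq_feature_cohort <- function(x, ...) {
  cat(sprintf("<slq_feature_cohort> %d participants x %d days, %d feature columns (seed %d)\n",
              nrow(x$participants), x$config$n_days,
              ncol(x$features) - 3L, x$config$seed))
  invisible(x)
}
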