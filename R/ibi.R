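#' Construct an interbeat-interval series
#'
#' An IBI series holds the beat stream a wrist/arm wearable reports: one row
#' per detected beat, with the timestamp at which the interval ends (seconds)
#' and the interval duration in milliseconds. Each beat carries a flag:
#' \code{"valid"}, \code{"artifact"} (detected, not yet repaired) or
#' \code{"interpolated"} (repaired by [interpolate_artifacts()]).
#'
#' @param time_s numeric, strictly increasing beat end-times in seconds.
#' @param ibi_ms numeric, positive interval durations in milliseconds.
#' @param flag character, per-beat flag; defaults to all \code{"valid"}.
#' @return A \code{data.frame} of class \code{ibi_series} with columns
#'   \code{time_s}, \code{ibi_ms}, \code{flag}.
#' @export
#' @examples
#' s <- ibi_series(cumsum(rep(0.8, 10)), rep(800, 10))
#' nrow(s)
ibi_series <- function(time_s, ibi_ms, flag = NULL) {
  time_s <- as.numeric(time_s)
  ibi_ms <- as.numeric(ibi_ms)
  if (length(time_s) != length(ibi_ms)) {
    stop("time_s and ibi_ms must have equal length")
  }
  if (length(time_s) && any(diff(time_s) <= 0)) {
    bad <- which(diff(time_s) <= 0)[1L] + 1L
    stop(sprintf("beat timestamps must be strictly increasing (row %d)", bad))
  }
  if (any(!is.finite(ibi_ms)) || any(ibi_ms <= 0)) {
    stop("ibi_ms must be finite and positive")
  }
  flag <- flag %||% rep("valid", length(ibi_ms))
  if (length(flag) != length(ibi_ms)) stop("flag must match ibi_ms in length")
  bad_flag <- setdiff(unique(flag), c("valid", "artifact", "interpolated"))
  if (length(bad_flag)) stop("unknown flag value: ", bad_flag[1L])
  structure(data.frame(time_s = time_s, ibi_ms = ibi_ms, flag = flag,
                       stringsAsFactors = FALSE),
            class = c("ibi_series", "data.frame"))
}

#' Artifact-detector settings
#'
#' Detection follows the quartile-deviation scheme used for beat-series
#' editing: a beat is suspect when its interval deviates from a robust local
#' expectation (a running median over \code{window_beats} neighbours) by more
#' than \code{criterion_mult} quartile deviations of the beat-to-beat
#' differences. The quartile deviation is floored at \code{qd_floor_ms} so a
#' metronomic stretch of the recording cannot drive the criterion to zero.
#'
#' @param criterion_mult multiplier applied to the quartile deviation;
#'   default 3.32, the conventional value derived for this class of detector.
#' @param window_beats odd window width (beats) of the local running median.
#' @param qd_floor_ms lower bound (ms) for the quartile deviation.
#' @param min_beats minimum series length the robust statistics need.
#' @return A list of class \code{artifact_params}.
#' @export
artifact_params <- function(criterion_mult = 3.32, window_beats = 5L,
                            qd_floor_ms = 10, min_beats = 12L) {
  stopifnot_scalar(criterion_mult, "criterion_mult", 0, Inf, strict_lo = TRUE)
  stopifnot_scalar(qd_floor_ms, "qd_floor_ms", 0, Inf, strict_lo = TRUE)
  window_beats <- as.integer(window_beats)
  if (window_beats < 3L) stop("'window_beats' must be >= 3")
  structure(list(criterion_mult = criterion_mult,
                 window_beats = window_beats,
                 qd_floor_ms = qd_floor_ms,
                 min_beats = as.integer(min_beats)),
            class = "artifact_params")
}

#' Detect interbeat-interval artifacts
#'
#' Flags beats whose interval deviates from a local running median by more
#' than \code{criterion_mult} times the quartile deviation of successive
#' interval differences. Missed beats (one interval absorbing its successor)
#' and ectopic splits (one interval divided in two) both produce deviations
#' of roughly half a beat or more and are the intended targets.
#'
#' @param series an [ibi_series()].
#' @param params an [artifact_params()] list.
#' @return Logical mask, \code{TRUE} where a beat is an artifact. The mask is
#'   deterministic: no randomness is involved.
#' @export
#' @examples
#' ib <- rep(800, 50); ib[25] <- 1600
#' s <- ibi_series(cumsum(ib) / 1000, ib)
#' which(detect_artifacts(s))
detect_artifacts <- function(series, params = artifact_params()) {
  if (!inherits(series, "ibi_series")) series <- as_ibi_series(series)
  n <- nrow(series)
  if (n < params$min_beats) {
    stop(sprintf("need at least %d beats for robust artifact statistics, got %d",
                 params$min_beats, n))
  }
  x <- series$ibi_ms
  local_med <- roll_med(x, params$window_beats)
  qd <- stats::IQR(diff(x)) / 2
  criterion <- params$criterion_mult * max(qd, params$qd_floor_ms)
  abs(x - local_med) > criterion
}

#' Linearly interpolate flagged beats
#'
#' Replaces every masked interval by linear interpolation (over beat index)
#' between the nearest unmasked neighbours; masked beats at either edge take
#' the nearest valid value. Replaced beats are flagged
#' \code{"interpolated"}; timestamps are left as recorded.
#'
#' @param series an [ibi_series()].
#' @param mask logical artifact mask aligned to \code{series}.
#' @return The repaired \code{ibi_series}.
#' @export
interpolate_artifacts <- function(series, mask) {
  if (!inherits(series, "ibi_series")) series <- as_ibi_series(series)
  mask <- as.logical(mask)
  if (length(mask) != nrow(series)) stop("mask must align with the series")
  if (!any(mask)) return(series)
  if (all(mask)) stop("every beat is flagged; nothing to interpolate from")
  idx <- seq_len(nrow(series))
  filled <- stats::approx(idx[!mask], series$ibi_ms[!mask], xout = idx[mask],
                          method = "linear", rule = 2)$y
  series$ibi_ms[mask] <- filled
  series$flag[mask] <- "interpolated"
  series
}

#' Poincare descriptors of one window
#'
#' For consecutive interval pairs \eqn{(x_i, x_{i+1})}: SD1 is the population
#' SD of the distances from the identity (45 degree) line of the Poincare
#' plot, \eqn{(x_{i+1}-x_i)/\sqrt2}; SD2 the population SD of distances from
#' the perpendicular (-45 degree) line, \eqn{(x_i+x_{i+1})/\sqrt2}; SDNN the
#' population SD of the intervals themselves.
#'
#' @param ibi_ms numeric vector of at least 3 interval durations (ms).
#' @return Named numeric vector \code{c(sd1, sd2, sdnn)} in ms.
#' @export
#' @examples
#' poincare_metrics(c(800, 600, 800, 600, 800))
poincare_metrics <- function(ibi_ms) {
  ibi_ms <- as.numeric(ibi_ms)
  if (length(ibi_ms) < 3L) {
    stop("Poincare metrics are undefined for fewer than 3 beats")
  }
  n <- length(ibi_ms)
  a <- ibi_ms[-n]
  b <- ibi_ms[-1L]
  c(sd1 = pop_sd((b - a) / sqrt(2)),
    sd2 = pop_sd((b + a) / sqrt(2)),
    sdnn = pop_sd(ibi_ms))
}

#' Chunk a beat series into non-overlapping 5-minute windows
#'
#' Windows tile the recording from its first beat timestamp in steps of
#' \code{window_s}; each beat belongs to exactly one window by its end-time
#' under the half-open convention \code{[start, end)}, and the trailing
#' partial window is discarded. Each window row carries its beat and
#' interpolation counts, mean heart rate (60000 / mean IBI, bpm) and the
#' Poincare descriptors (NA when the window has fewer than 3 beats).
#'
#' @param series a cleaned [ibi_series()].
#' @param window_s window length in seconds (default 300).
#' @return A \code{data.frame} of class \code{hrv_windows} with columns
#'   \code{start}, \code{end}, \code{n_beats}, \code{n_interpolated},
#'   \code{mean_hr}, \code{sd1}, \code{sd2}, \code{sdnn}, \code{kept}
#'   (initialised \code{NA}, set by [filter_windows()]); empty (zero rows)
#'   when the recording is shorter than one window.
#' @export
window_series <- function(series, window_s = 300) {
  if (!inherits(series, "ibi_series")) series <- as_ibi_series(series)
  stopifnot_scalar(window_s, "window_s", 0, Inf, strict_lo = TRUE)
  t0 <- series$time_s[1L]
  span <- series$time_s[nrow(series)] - t0
  n_win <- floor(span / window_s)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_beats = integer(0), n_interpolated = integer(0),
                      mean_hr = numeric(0), sd1 = numeric(0),
                      sd2 = numeric(0), sdnn = numeric(0), kept = logical(0))
  if (n_win < 1) return(structure(empty, class = c("hrv_windows", "data.frame")))
  win_id <- floor((series$time_s - t0) / window_s)
  rows <- lapply(seq_len(n_win) - 1L, function(w) {
    in_w <- win_id == w
    nb <- sum(in_w)
    ibi <- series$ibi_ms[in_w]
    met <- if (nb >= 3L) poincare_metrics(ibi) else c(sd1 = NA_real_, sd2 = NA_real_, sdnn = NA_real_)
    data.frame(start = t0 + w * window_s, end = t0 + (w + 1) * window_s,
               n_beats = nb,
               n_interpolated = sum(in_w & series$flag == "interpolated"),
               mean_hr = if (nb > 0) 60000 / mean(ibi) else NA_real_,
               sd1 = unname(met["sd1"]), sd2 = unname(met["sd2"]),
               sdnn = unname(met["sdnn"]), kept = NA)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("hrv_windows", "data.frame"))
}

#' Apply the interpolation-count exclusion rule
#'
#' A window is kept only when it contains at most \code{max_interpolated}
#' interpolated beats (default 4: windows with 5 or more repaired intervals
#' are dropped) and has enough beats for the descriptors to exist.
#'
#' @param windows output of [window_series()].
#' @param max_interpolated largest tolerated interpolated-beat count.
#' @return \code{windows} with the \code{kept} column populated.
#' @export
filter_windows <- function(windows, max_interpolated = 4L) {
  if (!is.data.frame(windows)) stop("'windows' must be a window data.frame")
  windows$kept <- windows$n_interpolated <= max_interpolated & windows$n_beats >= 3L
  windows
}

#' Clean a raw IBI stream and compute kept 5-minute HRV windows
#'
#' Convenience chain: [detect_artifacts()], [interpolate_artifacts()],
#' [window_series()], [filter_windows()].
#'
#' @inheritParams detect_artifacts
#' @inheritParams window_series
#' @inheritParams filter_windows
#' @return An \code{hrv_windows} data.frame with \code{kept} populated.
#' @export
compute_hrv_windows <- function(series, params = artifact_params(),
                                window_s = 300, max_interpolated = 4L) {
  mask <- detect_artifacts(series, params)
  if (any(mask)) series <- interpolate_artifacts(series, mask)
  filter_windows(window_series(series, window_s), max_interpolated)
}

as_ibi_series <- function(x) {
  if (!is.data.frame(x) || !all(c("time_s", "ibi_ms") %in% names(x))) {
    stop("expected an ibi_series or a data.frame with time_s and ibi_ms")
  }
  ibi_series(x$time_s, x$ibi_ms, if ("flag" %in% names(x)) x$flag else NULL)
}
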