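# CSV dialects (documented per stream):
#   ibi.csv:    timestamp_s, ibi_ms [, flag]
#   hr.csv:     timestamp_s, hr_bpm
#   accel.csv:  timestamp_s, magnitude
#   steps.csv:  timestamp_s, steps
#   stress.csv: participant, timestamp_s, stress
#   diary.csv:  participant, day, sleep_quality, awake_at_night, sleep_medication
#   participants.csv: id, age, sex, group, ms_type, edss, msss, armss,
#                     compass, spinal_cord
# All timestamps are numeric seconds from the cohort start in the
# participant's local clock (day boundaries are clock-sensitive because days
# are wake-anchored).

stream_schemas <- list(
  ibi = c("timestamp_s", "ibi_ms"),
  hr = c("timestamp_s", "hr_bpm"),
  accel = c("timestamp_s", "magnitude"),
  steps = c("timestamp_s", "steps"))

read_stream_csv <- function(path, kind) {
  need <- stream_schemas[[kind]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column '%s'", path, miss[1L]))
  }
  for (cl in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cl]]))))
    if (length(bad)) {
      stop(sprintf("%s: malformed value in column '%s' at data row %d",
                   path, cl, bad[1L]))
    }
    df[[cl]] <- as.numeric(df[[cl]])
  }
  if (any(diff(df$timestamp_s) <= 0)) {
    bad <- which(diff(df$timestamp_s) <= 0)[1L] + 1L
    stop(sprintf("%s: non-monotone timestamp at data row %d", path, bad))
  }
  df
}

#' Read one participant's stream bundle from a directory
#'
#' Expects \code{ibi.csv}, \code{hr.csv}, \code{accel.csv}, \code{steps.csv}
#' in the documented dialects; validates schemas and timestamp monotonicity,
#' reporting the offending column or row.
#'
#' @param path directory containing the four stream files.
#' @return List with \code{ibi} (an [ibi_series()]), \code{hr},
#'   \code{accel}, \code{steps} data.frames (column \code{time_s}).
#' @export
read_streams <- function(path) {
  out <- list()
  for (kind in names(stream_schemas)) {
    f <- file.path(path, paste0(kind, ".csv"))
    if (!file.exists(f)) stop("missing stream file: ", f)
    df <- read_stream_csv(f, kind)
    names(df)[names(df) == "timestamp_s"] <- "time_s"
    out[[kind]] <- df
  }
  flg <- if ("flag" %in% names(out$ibi)) out$ibi$flag else NULL
  out$ibi <- ibi_series(out$ibi$time_s, out$ibi$ibi_ms, flg)
  names(out$hr)[2] <- "hr_bpm"
  out
}

#' Write / read a simulated cohort as CSV plus a truth JSON sidecar
#'
#' One subdirectory per participant holding the four stream files, plus
#' cohort-level \code{participants.csv}, \code{diary.csv}, \code{stress.csv}
#' and \code{truth.json}. [read_cohort_csv()] restores an equivalent cohort
#' object; the round trip is lossless up to numeric printing precision
#' (values are written with full precision).
#'
#' @param cohort an \code{slq_cohort}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) utils::write.csv(format(df, digits = 15, trim = TRUE,
                                                scientific = FALSE),
                                         file.path(dir, f), row.names = FALSE,
                                         quote = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$diary, file.path(dir, "diary.csv"), row.names = FALSE)
  wr(data.frame(participant = cohort$stress$participant,
                timestamp_s = cohort$stress$time_s,
                stress = cohort$stress$stress), "stress.csv")
  for (id in names(cohort$streams)) {
    pd <- file.path(dir, id)
    dir.create(pd, showWarnings = FALSE)
    st <- cohort$streams[[id]]
    wr(data.frame(timestamp_s = st$ibi$time_s, ibi_ms = st$ibi$ibi_ms,
                  flag = st$ibi$flag), file.path(id, "ibi.csv"))
    wr(data.frame(timestamp_s = st$hr$time_s, hr_bpm = st$hr$hr_bpm),
       file.path(id, "hr.csv"))
    wr(data.frame(timestamp_s = st$accel$time_s, magnitude = st$accel$magnitude),
       file.path(id, "accel.csv"))
    wr(data.frame(timestamp_s = st$steps$time_s, steps = st$steps$steps),
       file.path(id, "steps.csv"))
  }
  truth <- cohort$truth
  jsonlite::write_json(list(bed_wake = truth$bed_wake,
                            artifacts = truth$artifacts,
                            features = truth$features,
                            labels = truth$labels,
                            effect_vector = as.list(truth$effect_vector),
                            ms_effect_vector = as.list(truth$ms_effect_vector)),
                       file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE)
  diary <- utils::read.csv(file.path(dir, "diary.csv"), stringsAsFactors = FALSE)
  stress_raw <- utils::read.csv(file.path(dir, "stress.csv"), stringsAsFactors = FALSE)
  stress <- data.frame(participant = stress_raw$participant,
                       time_s = as.numeric(stress_raw$timestamp_s),
                       stress = as.numeric(stress_raw$stress))
  streams <- lapply(participants$id, function(id) read_streams(file.path(dir, id)))
  names(streams) <- participants$id
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth$effect_vector <- unlist(truth$effect_vector)
  truth$ms_effect_vector <- unlist(truth$ms_effect_vector)
  structure(list(participants = participants, streams = streams,
                 stress = stress, diary = diary, truth = truth,
                 config = NULL),
            class = "slq_cohort")
}

#' Read or write a normative reference table
#'
#' CSV columns: sex, age_lo, age_hi, hour_lo, hour_hi, metric, mean, sd.
#'
#' @param path CSV path.
#' @export
read_normative_csv <- function(path) {
  normative_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_normative_csv
#' @param table a [normative_table()].
#' @export
write_normative_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every stage's constants (all defaulting to the analysis rules:
#' 300 s windows, at most 4 interpolated beats, resting rule
#' 0.55 x (220 - age), 1-hour trims, static cutoffs 3/3/4/17, 50 balanced
#' splits of 20% of participants, 0.5 probability cutoff) with the
#' simulation config and output paths.
#'
#' @param sim a [sim_config()] used when the pipeline simulates its input.
#' @param out_dir output directory; NULL for no file output.
#' @param input_dir optional cohort directory written by
#'   [write_cohort_csv()]; when given, the pipeline reads instead of
#'   simulating.
#' @param level \code{"streams"} (full signal chain) or \code{"features"}
#'   (feature-level generator; modelling-scale, no signal stages).
#' @param window_s,max_interpolated,resting_coef,hr_ceiling,trim_h,cutoffs
#'   stage constants.
#' @param detector [artifact_params()].
#' @param use_truth_periods pass the generator's true bed/wake times to the
#'   feature builder instead of estimating them.
#' @param penalty,selection_tol modelling constants.
#' @param n_splits,test_fraction evaluation plan.
#' @param min_group_participants smallest admissible group for the M2/M3
#'   group-wise fits.
#' @param scope model scopes to fit.
#' @param seed master seed for simulation, fold assignment and splits.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = NULL,
                            input_dir = NULL,
                            level = c("streams", "features"),
                            window_s = 300, max_interpolated = 4L,
                            resting_coef = 0.55, hr_ceiling = 220,
                            trim_h = 1,
                            cutoffs = c(edss = 3, msss = 3, armss = 4, compass = 17),
                            detector = artifact_params(),
                            use_truth_periods = FALSE,
                            penalty = NULL, selection_tol = 0.01,
                            n_splits = 50L, test_fraction = 0.20,
                            scope = c("both", "night", "day"),
                            min_group_participants = 5L,
                            seed = 1L) {
  level <- match.arg(level)
  structure(list(sim = sim, out_dir = out_dir, input_dir = input_dir,
                 level = level, window_s = window_s,
                 max_interpolated = as.integer(max_interpolated),
                 resting_coef = resting_coef, hr_ceiling = hr_ceiling,
                 trim_h = trim_h, cutoffs = cutoffs, detector = detector,
                 use_truth_periods = use_truth_periods,
                 penalty = penalty, selection_tol = selection_tol,
                 n_splits = as.integer(n_splits), test_fraction = test_fraction,
                 scope = scope,
                 min_group_participants = as.integer(min_group_participants),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort, builds the daily feature table, normalizes
#' per participant, checks response normality, fits the M1/M2/M3 model
#' families, evaluates the penalized logistic model on balanced
#' subject-held-out splits, and computes the subgroup report. Fully
#' deterministic given the config's seed. When \code{out_dir} is set, each
#' stage's table is written as CSV together with a JSON manifest (config
#' hash, seed, package version).
#'
#' @param config a [pipeline_config()].
#' @return List of class \code{slq_pipeline}: \code{features}, \code{norm},
#'   \code{normality}, \code{fits} (named by family), \code{family_tables},
#'   \code{eval}, \code{subgroups}, \code{manifest}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stop("'config' must be a pipeline_config")
  stage <- "simulate"
  res <- tryCatch({
    if (!is.null(config$input_dir)) {
      cohort <- read_cohort_csv(config$input_dir)
      participants <- binarize_static(cohort$participants, config$cutoffs)
      stage <- "features"
      features <- build_daily_features(cohort,
                                       use_truth_periods = config$use_truth_periods,
                                       detector = config$detector)
    } else if (config$level == "streams") {
      cohort <- simulate_cohort(config$sim)
      participants <- binarize_static(cohort$participants, config$cutoffs)
      stage <- "features"
      features <- build_daily_features(cohort,
                                       use_truth_periods = config$use_truth_periods,
                                       detector = config$detector)
    } else {
      cohort <- simulate_feature_cohort(config$sim)
      participants <- binarize_static(cohort$participants, config$cutoffs)
      features <- merge(cohort$features,
                        participants[, c("id", "group", "sex", "age",
                                         "edss_severe", "msss_severe",
                                         "armss_severe", "ans_dysfunction",
                                         "spinal_cord")],
                        by.x = "participant", by.y = "id", sort = FALSE)
    }

    stage <- "normalize"
    keep <- intersect(c("group", "sex", "age", "edss_severe", "msss_severe",
                        "armss_severe", "ans_dysfunction", "spinal_cord"),
                      names(features))
    norm <- suppressWarnings(
      normalize_per_participant(features, keep = keep))
    normality <- tryCatch(check_response_normality(norm$data$sleep_quality),
                          error = function(e) NULL)

    stage <- "fit"
    fits <- lapply(c(M1 = "M1", M2 = "M2", M3 = "M3"), function(fam) {
      fit_model_family(norm, scope = config$scope, family = fam,
                       penalty = config$penalty,
                       min_group_participants = config$min_group_participants,
                       seed = config$seed)
    })

    stage <- "evaluate"
    dat <- norm$data
    dat$label <- binarize_sleep_quality(dat$sleep_quality)
    both_cols <- scope_columns(setdiff(norm$columns, "sleep_quality"), "both")
    both_cols <- both_cols[colMeans(is.na(dat[, both_cols, drop = FALSE])) <= 0.5]
    cc <- stats::complete.cases(dat[, c(both_cols, "label")])
    dat <- dat[cc, , drop = FALSE]
    splits <- make_balanced_splits(dat, n_splits = config$n_splits,
                                   test_fraction = config$test_fraction,
                                   seed = config$seed)
    m11 <- fits$M1[[grep("^M1\\.1$", names(fits$M1), value = TRUE)[1]]]
    eval_rep <- evaluate_model(dat, splits, both_cols,
                               contract = l1_logistic_contract(penalty = m11$penalty),
                               label_col = "label")

    stage <- "subgroups"
    subgroups <- subgroup_report(features, participants)

    manifest <- list(seed = config$seed,
                     package_version = as.character(utils::packageVersion("hrvsleep")),
                     level = if (!is.null(config$input_dir)) "read" else config$level,
                     n_participants = length(unique(features$participant)),
                     n_days_total = nrow(features))
    out <- structure(list(features = features, norm = norm,
                          normality = normality, fits = fits,
                          family_tables = lapply(fits, family_table),
                          eval = eval_rep, subgroups = subgroups,
                          manifest = manifest),
                     class = "slq_pipeline")
    if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
    out
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  res
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$features, file.path(config$out_dir, "daily_features.csv"),
                   row.names = FALSE)
  for (fam in names(res$family_tables)) {
    utils::write.csv(res$family_tables[[fam]],
                     file.path(config$out_dir, sprintf("model_%s.csv", fam)),
                     row.names = FALSE)
  }
  utils::write.csv(res$eval$per_split, file.path(config$out_dir, "eval_splits.csv"),
                   row.names = FALSE)
  agg <- as.data.frame(t(res$eval$aggregate))
  utils::write.csv(agg, file.path(config$out_dir, "eval_aggregate.csv"),
                   row.names = FALSE)
  utils::write.csv(res$subgroups, file.path(config$out_dir, "subgroups.csv"),
                   row.names = FALSE)
  cfg_path <- file.path(config$out_dir, "config.json")
  cfg <- config
  cfg$detector <- unclass(cfg$detector)
  cfg$sim <- lapply(unclass(cfg$sim), function(v) if (is.numeric(v)) v else as.character(v))
  jsonlite::write_json(cfg[!vapply(cfg, is.function, TRUE)], cfg_path,
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  res$manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(res$manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(config$out_dir)
}

#' @export
print.slq_pipeline <- function(x, ...) {
  cat(sprintf("<slq_pipeline> %d participant-days, %d participants\n",
              x$manifest$n_days_total, x$manifest$n_participants))
  if (!is.null(x$normality)) cat("  normality: ", x$normality$message, "\n", sep = "")
  print(x$eval)
  invisible(x)
}
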