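#' Columns belonging to a model input scope
#'
#' The model families differ in what information they may see: \code{night}
#' uses everything recorded while participants slept (columns ending in
#' \code{_asleep}, plus \code{sleep_duration}, \code{awake_at_night},
#' \code{sleep_medication}); \code{day} everything recorded awake (columns
#' ending in \code{_awake}, plus \code{awake_duration}); \code{both} the
#' union.
#'
#' @param columns candidate column names.
#' @param scope \code{"both"}, \code{"night"} or \code{"day"}.
#' @return The subset of \code{columns} visible to the scope.
#' @export
scope_columns <- function(columns, scope = c("both", "night", "day")) {
  scope <- match.arg(scope)
  night <- columns[endsWith(columns, "_asleep") |
                     columns %in% c("sleep_duration", "awake_at_night",
                                    "sleep_medication")]
  day <- columns[endsWith(columns, "_awake") | columns %in% "awake_duration"]
  switch(scope, both = union(night, day), night = night, day = day)
}

#' Fit the M1/M2/M3 model families
#'
#' Three families of per-participant-normalized logistic sleep-quality
#' models, each available with night-and-day, night-only, or day-only
#' inputs (suffixes .1/.2/.3):
#' \describe{
#'   \item{M1}{one joint fit over every participant; the L1 penalty performs
#'     the feature selection.}
#'   \item{M2}{the M1-selected features, refitted separately per group
#'     (effect stability under fixed features).}
#'   \item{M3}{feature selection and fit both performed per group
#'     (group-optimised models).}
#' }
#' Reported coefficients and p-values come from unpenalized refits on the
#' selected features; the conventional reporting threshold is P < .10.
#'
#' @param norm a \code{normalized_matrix} from [normalize_per_participant()]
#'   whose data contain the scope columns and the response.
#' @param scope model input scope(s), any of \code{"both"}, \code{"night"},
#'   \code{"day"}; default all three.
#' @param family \code{"M1"}, \code{"M2"} or \code{"M3"}.
#' @param group per-row group labels (e.g. \code{"MS"}/\code{"control"}),
#'   required for M2/M3; taken from column \code{group} of the data when
#'   present.
#' @param response normalized response column, default
#'   \code{"sleep_quality"}.
#' @param penalty fixed lasso penalty; NULL chooses per fit by grouped CV.
#' @param min_group_participants smallest admissible group, default 5.
#' @param seed CV fold seed.
#' @return List of class \code{slq_family} of [fit_l1_logistic()] fits, each
#'   annotated with \code{model_id} (e.g. \code{"M3.2"}), \code{scope} and
#'   \code{group}.
#' @export
fit_model_family <- function(norm, scope = c("both", "night", "day"),
                             family = c("M1", "M2", "M3"), group = NULL,
                             response = "sleep_quality", penalty = NULL,
                             min_group_participants = 5L, seed = 1L) {
  family <- match.arg(family)
  scope <- match.arg(scope, several.ok = TRUE)
  if (!inherits(norm, "normalized_matrix")) stop("'norm' must be a normalized_matrix")
  df <- norm$data
  group <- group %||% df$group
  if (family != "M1" && is.null(group)) stop("'group' is required for ", family)
  ids <- df[[norm$id_col]]
  y_all <- binarize_sleep_quality(df[[response]])
  feat_cols <- setdiff(norm$columns, response)
  scope_idx <- c(both = 1L, night = 2L, day = 3L)

  fits <- list()
  for (sc in scope) {
    cols <- scope_columns(feat_cols, sc)
    if (!length(cols)) stop("no candidate columns for scope '", sc, "'")
    # person-constant variables (e.g. a medication taken every night) carry
    # no within-participant signal and are mostly NA after normalization;
    # drop columns losing over half their rows rather than the rows
    na_frac <- colMeans(is.na(df[, cols, drop = FALSE]))
    cols <- cols[na_frac <= 0.5]
    if (!length(cols)) stop("scope '", sc, "' has no usable (within-person varying) columns")
    cc <- stats::complete.cases(df[, cols, drop = FALSE]) & !is.na(y_all)
    x <- df[cc, cols, drop = FALSE]
    y <- y_all[cc]
    id <- ids[cc]
    gr <- if (!is.null(group)) group[cc] else NULL
    if (family == "M1") {
      f <- fit_l1_logistic(x, y, penalty = penalty, groups = id, seed = seed)
      f$model_id <- sprintf("M1.%d", scope_idx[[sc]])
      f$scope <- sc; f$group <- "all"
      fits[[f$model_id]] <- f
    } else if (family == "M2") {
      base <- fit_l1_logistic(x, y, penalty = penalty, groups = id, seed = seed)
      for (g in unique(gr)) {
        check_group_size(id, gr, g, min_group_participants)
        sel <- gr == g
        f <- refit_on(x[sel, base$selected, drop = FALSE], y[sel], base)
        f$model_id <- sprintf("M2.%d", scope_idx[[sc]])
        f$scope <- sc; f$group <- g
        fits[[paste(f$model_id, g, sep = ":")]] <- f
      }
    } else {
      for (g in unique(gr)) {
        check_group_size(id, gr, g, min_group_participants)
        sel <- gr == g
        f <- fit_l1_logistic(x[sel, , drop = FALSE], y[sel], penalty = penalty,
                             groups = id[sel], seed = seed)
        f$model_id <- sprintf("M3.%d", scope_idx[[sc]])
        f$scope <- sc; f$group <- g
        fits[[paste(f$model_id, g, sep = ":")]] <- f
      }
    }
  }
  structure(fits, class = "slq_family")
}

check_group_size <- function(id, gr, g, min_participants) {
  n <- length(unique(id[gr == g]))
  if (n < min_participants) {
    stop(sprintf("group '%s' has only %d participants (minimum %d)",
                 g, n, min_participants))
  }
  invisible(n)
}

# unpenalized refit on a fixed feature set (M2 path)
refit_on <- function(x, y, base) {
  if (length(unique(y)) < 2L) stop("response has a single class in this group")
  if (ncol(x)) {
    refit <- stats::glm(.y ~ ., data = data.frame(x, .y = y),
                        family = stats::binomial())
  } else {
    refit <- stats::glm(y ~ 1, family = stats::binomial())
  }
  sm <- summary(refit)$coefficients
  structure(list(selected = colnames(x), coefficients = sm[, "Estimate"],
                 p_values = sm[, "Pr(>|z|)"], penalty = base$penalty,
                 cutoff = 0.5, n = length(y), separation = FALSE,
                 lasso = NULL, refit = refit, feature_names = colnames(x),
                 note = "group refit on jointly selected features",
                 model_id = NA_character_, scope = NA_character_,
                 group = "all"),
            class = "slq_fit")
}

#' @export
print.slq_family <- function(x, ...) {
  cat(sprintf("<slq_family> %d fit(s)\n", length(x)))
  for (f in x) print(f)
  invisible(x)
}

#' Tabulate a model family like a results table
#'
#' One row per feature and fit, keeping features significant below
#' \code{p_report} in at least one fit (the usual table convention).
#'
#' @param family an \code{slq_family}.
#' @param p_report reporting threshold on p-values, default 0.10.
#' @param all_features keep every selected feature regardless of p.
#' @return data.frame with \code{model_id}, \code{group}, \code{feature},
#'   \code{coefficient}, \code{p_value}.
#' @export
family_table <- function(family, p_report = 0.10, all_features = FALSE) {
  rows <- list()
  for (f in family) {
    cf <- f$coefficients
    keep <- setdiff(names(cf), "(Intercept)")
    if (length(keep)) {
      rows[[length(rows) + 1L]] <-
        data.frame(model_id = f$model_id, group = f$group, feature = keep,
                   coefficient = unname(cf[keep]),
                   p_value = unname(f$p_values[keep]),
                   stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model_id = character(0), group = character(0),
               feature = character(0), coefficient = numeric(0),
               p_value = numeric(0))
  if (!all_features && nrow(tab)) {
    sig_features <- unique(tab$feature[tab$p_value < p_report])
    tab <- tab[tab$feature %in% sig_features, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}
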