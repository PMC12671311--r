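#' Per-participant normalization of the daily feature table
#'
#' Each retained column is z-scored within participant: the participant's
#' mean over the study is subtracted and the result divided by the
#' participant's sample SD (n-1 denominator). Models fitted on the result
#' therefore explain within-person change, not between-person level.
#' Columns that are constant for a participant (SD = 0) are set to missing
#' for that participant and recorded; participants with fewer than 2
#' non-missing days in a column are dropped from it with a warning.
#'
#' @param features data.frame with one row per participant-day.
#' @param id_col participant identifier column, default \code{"participant"}.
#' @param cols columns to normalize; default all numeric columns except the
#'   identifiers and any in \code{keep}.
#' @param keep columns carried through untouched (grouping variables,
#'   static flags).
#' @return List of class \code{normalized_matrix}: \code{data} (identifiers,
#'   kept columns, normalized columns), \code{centers} and \code{scales}
#'   (per participant x column, for denormalization), \code{dropped}
#'   (participant/column pairs lost to zero SD or short records).
#' @export
#' @examples
#' df <- data.frame(participant = rep("a", 3), sleep_quality = c(3, 4, 5))
#' normalize_per_participant(df)$data$sleep_quality
normalize_per_participant <- function(features, id_col = "participant",
                                      cols = NULL, keep = character()) {
  if (!id_col %in% names(features)) stop("missing id column '", id_col, "'")
  auto <- vapply(features, is.numeric, TRUE)
  cols <- cols %||% setdiff(names(features)[auto], c(id_col, "day", keep))
  id <- features[[id_col]]
  uid <- unique(id)
  centers <- scales <- matrix(NA_real_, length(uid), length(cols),
                              dimnames = list(uid, cols))
  dropped <- list()
  data <- features[, intersect(c(id_col, "day", keep), names(features)), drop = FALSE]
  for (cl in cols) {
    v <- features[[cl]]
    out <- rep(NA_real_, length(v))
    for (u in uid) {
      sel <- id == u & !is.na(v)
      if (sum(sel) < 2L) {
        if (any(id == u)) {
          dropped[[length(dropped) + 1L]] <-
            data.frame(participant = u, column = cl, reason = "fewer than 2 days")
          warning(sprintf("participant %s dropped from '%s': fewer than 2 non-missing days",
                          u, cl), call. = FALSE)
        }
        next
      }
      mu <- mean(v[sel]); sdv <- stats::sd(v[sel])
      centers[u, cl] <- mu; scales[u, cl] <- sdv
      if (sdv == 0) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(participant = u, column = cl, reason = "zero within-participant SD")
        next
      }
      out[sel] <- (v[sel] - mu) / sdv
    }
    data[[cl]] <- out
  }
  structure(list(data = data, centers = centers, scales = scales,
                 columns = cols, id_col = id_col,
                 dropped = if (length(dropped)) do.call(rbind, dropped) else
                   data.frame(participant = character(0), column = character(0),
                              reason = character(0))),
            class = "normalized_matrix")
}

#' Invert a per-participant normalization
#'
#' @param norm a \code{normalized_matrix}.
#' @return data.frame on the original scale (missing where values were
#'   dropped).
#' @export
denormalize <- function(norm) {
  out <- norm$data
  id <- out[[norm$id_col]]
  for (cl in norm$columns) {
    out[[cl]] <- out[[cl]] * norm$scales[id, cl] + norm$centers[id, cl]
  }
  out
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d rows, %d normalized columns, %d drop records\n",
              nrow(x$data), length(x$columns), nrow(x$dropped)))
  invisible(x)
}

#' Binarize the normalized sleep-quality response
#'
#' High-quality sleep is a night strictly better than the participant's
#' personal average, i.e. a positive normalized response; a night exactly at
#' the average (normalized 0) is low.
#'
#' @param normalized_response numeric normalized response values.
#' @return Integer vector, 1 = high, 0 = low, \code{NA} preserved.
#' @export
binarize_sleep_quality <- function(normalized_response) {
  ifelse(is.na(normalized_response), NA_integer_,
         as.integer(normalized_response > 0))
}

#' Shapiro-Wilk check of the normalized response
#'
#' The modelling pathway treats sleep quality as binary because the
#' normalized 1-5 response is discrete and fails normality; this helper
#' performs that check and returns the justification message.
#'
#' @param normalized_response numeric vector, n >= 3 (at most 5000 values
#'   are used, sampled deterministically from the head of the vector).
#' @return List: \code{statistic} (W), \code{p_value}, \code{normal}
#'   (p > .05), \code{message}. Constant input is an error (the statistic is
#'   undefined).
#' @export
check_response_normality <- function(normalized_response) {
  x <- normalized_response[!is.na(normalized_response)]
  if (length(x) < 3L) stop("normality check needs at least 3 values")
  if (length(x) > 5000L) x <- x[seq_len(5000L)]
  if (stats::sd(x) == 0) stop("response is constant; normality test undefined")
  sw <- stats::shapiro.test(x)
  normal <- sw$p.value > 0.05
  list(statistic = unname(sw$statistic), p_value = sw$p.value, normal = normal,
       message = if (normal) {
         "response consistent with normality; linear modelling admissible"
       } else {
         "normalized response fails Shapiro-Wilk normality; modelling the binary high/low split instead"
       })
}

#' Fit an L1-penalized logistic sleep-quality model
#'
#' The lasso path performs feature selection: coefficients without
#' explanatory power shrink to exactly zero at the chosen penalty. Reported
#' coefficients and Wald p-values come from an unpenalized logistic refit on
#' the surviving features (no post-selection correction is applied; the
#' p-values are conventional and recorded as such in the fit metadata).
#'
#' @param x data.frame or matrix of normalized features (no missing values
#'   in the used columns), or a \code{normalized_matrix}.
#' @param y binary response (0/1 or logical), both classes present.
#' @param penalty lasso penalty \eqn{\lambda}. \code{NULL} (default) selects
#'   it along the path by extended BIC (\code{gamma = 0.5}), which is
#'   selection-consistent for sparse supports and fully deterministic;
#'   \code{"cv"} instead uses participant-grouped cross-validated binomial
#'   deviance with the one-standard-error rule; a number fixes it.
#' @param groups participant ids per row, used to build grouped CV folds so
#'   no participant straddles folds; required for \code{penalty = "cv"}
#'   unless \code{x} is a \code{normalized_matrix}.
#' @param nfolds CV folds for penalty selection, default 10.
#' @param seed seed controlling CV fold assignment, default 1 (unused by the
#'   EBIC rule, which has no randomness).
#' @param ebic_gamma extended-BIC feature-space weight in [0, 1].
#' @return Object of class \code{slq_fit}: selected features, refit
#'   coefficients (log-odds per 1 within-participant SD), p-values, penalty,
#'   classification cutoff 0.5, and the underlying fits.
#' @export
fit_l1_logistic <- function(x, y, penalty = NULL, groups = NULL,
                            nfolds = 10L, seed = 1L, ebic_gamma = 0.5) {
  if (inherits(x, "normalized_matrix")) {
    groups <- groups %||% x$data[[x$id_col]]
    x <- x$data[, x$columns, drop = FALSE]
  }
  x <- as.data.frame(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("x and y must align")
  if (anyNA(x) || anyNA(y)) stop("missing cells in the modelling columns; subset to complete cases first")
  if (length(unique(y)) < 2L) stop("response has a single class; cannot fit")
  xm <- as.matrix(x)
  if (min(table(y)) < 2L) {
    # one class is a single observation: no basis for selection, fall back
    # to the intercept-only model rather than a spurious support
    refit <- stats::glm(y ~ 1, family = stats::binomial())
    return(structure(list(selected = character(0),
                          coefficients = stats::coef(refit),
                          p_values = summary(refit)$coefficients[, "Pr(>|z|)"],
                          penalty = NA_real_, cutoff = 0.5, n = nrow(x),
                          separation = FALSE, lasso = NULL, refit = refit,
                          feature_names = colnames(xm),
                          note = "degenerate class counts; intercept-only fallback",
                          model_id = NA_character_, scope = NA_character_,
                          group = "all"),
                     class = "slq_fit"))
  }
  path <- glmnet::glmnet(xm, y, family = "binomial", alpha = 1,
                         standardize = FALSE)
  if (is.null(penalty)) {
    penalty <- ebic_penalty(path, xm, y, ebic_gamma)
  } else if (identical(penalty, "cv")) {
    if (is.null(groups)) stop("'groups' is required to choose the penalty by grouped CV")
    foldid <- grouped_foldid(groups, nfolds, seed)
    cv <- glmnet::cv.glmnet(xm, y, family = "binomial", alpha = 1,
                            foldid = foldid, standardize = FALSE)
    penalty <- cv$lambda.1se
  }
  # coefficients from the fitted path: a one-lambda glmnet call is
  # numerically unreliable near lambda_max
  beta <- as.numeric(stats::coef(path, s = penalty, exact = FALSE))[-1L]
  selected <- colnames(xm)[beta != 0]
  gfit <- path

  separation <- FALSE
  if (length(selected)) {
    dat <- data.frame(x[, selected, drop = FALSE], .y = y)
    refit <- withCallingHandlers(
      stats::glm(.y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (separation) {
      warning("possible perfect separation in the unpenalized refit; coefficients reported with caution",
              call. = FALSE)
    }
    sm <- summary(refit)$coefficients
    coefs <- sm[, "Estimate"]
    pvals <- sm[, "Pr(>|z|)"]
  } else {
    refit <- stats::glm(y ~ 1, family = stats::binomial())
    coefs <- stats::coef(refit)
    pvals <- summary(refit)$coefficients[, "Pr(>|z|)"]
  }
  structure(list(selected = selected, coefficients = coefs, p_values = pvals,
                 penalty = penalty, cutoff = 0.5, n = nrow(x),
                 separation = separation, lasso = gfit, refit = refit,
                 feature_names = colnames(xm),
                 note = "p-values from unpenalized refit on the L1-surviving set; no post-selection correction",
                 model_id = NA_character_, scope = NA_character_,
                 group = "all"),
            class = "slq_fit")
}

# extended BIC (Chen & Chen 2008) along the lasso path: for each distinct
# support, deviance of the unpenalized refit plus df * (log n + 2 gamma log p);
# the penalty of the minimising support is returned
ebic_penalty <- function(path, xm, y, gamma) {
  n <- nrow(xm); p <- ncol(xm)
  bm <- as.matrix(path$beta) != 0
  keys <- apply(bm, 2, function(b) paste(which(b), collapse = ","))
  best <- Inf
  best_lam <- path$lambda[1L]
  for (j in which(!duplicated(keys))) {
    sup <- which(bm[, j])
    dev <- if (length(sup)) {
      stats::deviance(stats::glm(.y ~ ., family = stats::binomial(),
                                 data = data.frame(xm[, sup, drop = FALSE], .y = y)))
    } else {
      stats::deviance(stats::glm(y ~ 1, family = stats::binomial()))
    }
    crit <- dev + length(sup) * (log(n) + 2 * gamma * log(p))
    if (crit < best) {
      best <- crit
      best_lam <- path$lambda[j]
    }
  }
  best_lam
}

grouped_foldid <- function(groups, nfolds, seed) {
  ug <- unique(groups)
  nfolds <- min(nfolds, length(ug))
  with_seed(seed, {
    fold_of_group <- sample(rep(seq_len(nfolds), length.out = length(ug)))
  })
  fold_of_group[match(groups, ug)]
}

#' @export
print.slq_fit <- function(x, ...) {
  hdr <- if (!is.na(x$model_id)) sprintf(" %s (%s, %s)", x$model_id, x$scope, x$group) else ""
  cat(sprintf("<slq_fit>%s  n = %d, penalty = %.4g, %d feature(s) selected\n",
              hdr, x$n, x$penalty, length(x$selected)))
  if (length(x$selected)) {
    cat("  ", paste(x$selected, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.slq_fit <- function(object, p_report = 0.10, ...) {
  cf <- object$coefficients
  tab <- data.frame(feature = names(cf), coefficient = unname(cf),
                    p_value = unname(object$p_values[names(cf)]),
                    stringsAsFactors = FALSE)
  tab$significant <- tab$p_value < p_report
  structure(list(table = tab, p_report = p_report, fit = object),
            class = "summary.slq_fit")
}

#' @export
print.summary.slq_fit <- function(x, ...) {
  print(x$fit)
  tab <- x$table
  tab$coefficient <- sprintf("% .3f", tab$coefficient)
  tab$p_value <- ifelse(x$table$p_value < 0.001, "<.001",
                        ifelse(x$table$p_value < 0.01,
                               sub("^0", "", sprintf("%.3f", x$table$p_value)),
                               sub("^0", "", sprintf("%.2f", x$table$p_value))))
  tab$significant <- ifelse(x$table$significant, "*", "")
  print(tab, row.names = FALSE)
  cat(sprintf("  * P < %.2f (reporting convention)\n", x$p_report))
  invisible(x)
}

#' @export
coef.slq_fit <- function(object, ...) object$coefficients

#' Predict from an L1 sleep-quality fit
#'
#' @param object an \code{slq_fit}.
#' @param newdata data.frame containing the selected features.
#' @param type \code{"response"} (probability of high-quality sleep),
#'   \code{"link"}, or \code{"class"} (threshold at the 0.5 cutoff).
#' @param ... unused.
#' @export
predict.slq_fit <- function(object, newdata,
                            type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  p <- as.numeric(stats::predict(object$refit, newdata = as.data.frame(newdata),
                                 type = if (type == "link") "link" else "response"))
  if (type == "class") as.integer(p > object$cutoff) else p
}

#' Greedy sequential forward feature selection
#'
#' Adds at each step the candidate whose addition maximises
#' participant-grouped cross-validated AUC, stopping when no candidate
#' improves the AUC by more than \code{tol}. AUC ties between candidates are
#' broken lexicographically by feature name, making the procedure invariant
#' to column order; fold assignment is the only randomness and is fixed by
#' \code{seed}.
#'
#' @param x data.frame of candidate features (complete cases).
#' @param y binary response.
#' @param groups participant ids per row (grouped folds).
#' @param contract a classifier plug-in from [logistic_contract()]:
#'   \code{fit(x, y)} and \code{predict_probability(model, x)}, both
#'   deterministic given a seed.
#' @param tol minimum CV-AUC improvement to continue, default 0.01.
#' @param nfolds CV folds, default 5.
#' @param max_features optional cap on the selected-set size.
#' @param seed fold-assignment seed.
#' @return Character vector of selected features in selection order, with
#'   attribute \code{"auc_path"} giving the CV AUC after each addition.
#' @export
sequential_feature_selection <- function(x, y, groups,
                                         contract = logistic_contract(),
                                         tol = 0.01, nfolds = 5L,
                                         max_features = ncol(x), seed = 1L) {
  x <- as.data.frame(x)
  if (ncol(x) == 0L) stop("empty candidate feature set")
  foldid <- grouped_foldid(groups, nfolds, seed)
  cand <- sort(names(x))
  chosen <- character(0)
  best_auc <- 0.5
  path <- numeric(0)
  repeat {
    if (!length(cand) || length(chosen) >= max_features) break
    aucs <- vapply(cand, function(f) {
      cols <- c(chosen, f)
      cv_auc(x[, cols, drop = FALSE], y, foldid, contract)
    }, 0)
    top <- cand[which.max(aucs)]  # which.max takes the first (lexicographic) tie
    if (max(aucs) - best_auc <= tol) break
    best_auc <- max(aucs)
    chosen <- c(chosen, top)
    path <- c(path, best_auc)
    cand <- setdiff(cand, top)
  }
  attr(chosen, "auc_path") <- path
  chosen
}

cv_auc <- function(x, y, foldid, contract) {
  scores <- rep(NA_real_, length(y))
  for (f in unique(foldid)) {
    tr <- foldid != f
    if (length(unique(y[tr])) < 2L) next
    m <- contract$fit(x[tr, , drop = FALSE], y[tr])
    scores[!tr] <- contract$predict_probability(m, x[!tr, , drop = FALSE])
  }
  ok <- !is.na(scores)
  if (length(unique(y[ok])) < 2L) return(0.5)
  auc(scores[ok], y[ok])
}

#' Classifier plug-in contract: plain logistic regression
#'
#' The evaluation and selection machinery accept any model through a small
#' contract: \code{fit(x, y)} returning a model object and
#' \code{predict_probability(model, x)} returning probabilities in [0, 1],
#' both deterministic given a seed. This constructor provides the default
#' (unpenalized logistic regression); [l1_logistic_contract()] wraps the
#' penalized fit.
#'
#' @return List with elements \code{fit}, \code{predict_probability},
#'   \code{label}.
#' @export
logistic_contract <- function() {
  list(fit = function(x, y) {
    stats::glm(.y ~ ., data = data.frame(x, .y = y), family = stats::binomial())
  },
  predict_probability = function(model, x) {
    as.numeric(stats::predict(model, newdata = as.data.frame(x), type = "response"))
  },
  label = "logistic")
}

#' @rdname logistic_contract
#' @param penalty fixed lasso penalty; NULL re-selects by grouped CV inside
#'   each training fit (requires a \code{groups} attribute on \code{x}).
#' @param seed seed forwarded to penalty selection.
#' @export
l1_logistic_contract <- function(penalty = NULL, seed = 1L) {
  list(fit = function(x, y) {
    fit_l1_logistic(x, y, penalty = penalty,
                    groups = attr(x, "groups") %||% seq_len(nrow(x)),
                    seed = seed)
  },
  predict_probability = function(model, x) {
    predict(model, newdata = x, type = "response")
  },
  label = "l1_logistic")
}
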