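#' Area under the ROC curve by pairwise concordance
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half — computed via the rank-sum
#' identity, equivalent to enumerating all positive x negative pairs.
#'
#' @param scores numeric scores (probabilities or any monotone transform;
#'   AUC is invariant to strictly monotone rescoring).
#' @param labels binary labels (1 = positive), both classes present.
#' @return AUC in [0, 1].
#' @export
#' @examples
#' auc(c(.9, .8, .2, .1), c(1, 1, 0, 0))
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels must align")
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) stop("AUC needs both classes present")
  r <- rank(scores)  # average ranks give the tie = 1/2 convention
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Plan repeated perfectly balanced subject-held-out test sets
#'
#' For each split, \code{ceiling(test_fraction x n_participants)}
#' participants are sampled without replacement as the test set and removed
#' from training entirely; within their rows the majority class is
#' downsampled (without replacement) so the realized test set has exactly
#' equal high/low counts. A draw whose held-out rows are single-class is
#' resampled a bounded number of times before erroring.
#'
#' @param data data.frame with a participant id column and a binary label
#'   column.
#' @param n_splits number of splits, default 50.
#' @param test_fraction fraction of participants held out, default 0.20.
#' @param id_col,label_col column names, defaults \code{"participant"} and
#'   \code{"label"}.
#' @param seed RNG seed; the realized plan is a deterministic function of it.
#' @param max_retries resampling attempts per split for degenerate draws.
#' @return List of class \code{split_plan}; each element has
#'   \code{test_participants}, \code{test_rows} (balanced row indices into
#'   \code{data}), \code{train_rows}.
#' @export
make_balanced_splits <- function(data, n_splits = 50L, test_fraction = 0.20,
                                 id_col = "participant", label_col = "label",
                                 seed = 1L, max_retries = 100L) {
  ids <- data[[id_col]]
  y <- as.integer(data[[label_col]])
  uid <- unique(ids)
  n_test <- ceiling(test_fraction * length(uid))
  with_seed(seed, {
    splits <- vector("list", n_splits)
    for (s in seq_len(n_splits)) {
      for (attempt in seq_len(max_retries)) {
        test_p <- sample(uid, n_test)
        rows <- which(ids %in% test_p & !is.na(y))
        if (length(unique(y[rows])) == 2L) break
        if (attempt == max_retries) {
          stop("could not draw a two-class held-out set after ", max_retries,
               " attempts")
        }
      }
      pos <- rows[y[rows] == 1L]
      neg <- rows[y[rows] == 0L]
      k <- min(length(pos), length(neg))
      test_rows <- c(if (length(pos) > k) sample(pos, k) else pos,
                     if (length(neg) > k) sample(neg, k) else neg)
      splits[[s]] <- list(test_participants = test_p,
                          test_rows = sort(test_rows),
                          train_rows = which(!(ids %in% test_p) & !is.na(y)))
    }
    structure(splits, class = "split_plan",
              seed = seed, test_fraction = test_fraction)
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d balanced subject-held-out splits (%.0f%% of participants, seed %d)\n",
              length(x), 100 * attr(x, "test_fraction"), attr(x, "seed")))
  invisible(x)
}

#' Evaluate a classifier over a balanced split plan
#'
#' Per split: fit the plug-in model on the training rows, score the balanced
#' held-out rows, threshold probabilities at the 0.5 cutoff for accuracy,
#' precision and recall (positive class = high-quality sleep), and compute
#' AUC from the raw scores. Aggregates are the means over splits.
#'
#' @param data data.frame with the feature columns, id column and label.
#' @param splits a [make_balanced_splits()] plan on the same data.
#' @param features feature column names used by the model.
#' @param contract classifier plug-in ([logistic_contract()] by default).
#' @param id_col,label_col column names as in the plan.
#' @return List of class \code{eval_report}: \code{per_split} data.frame
#'   (accuracy/precision/recall in %, auc), \code{aggregate} named means,
#'   \code{cutoff}.
#' @export
evaluate_model <- function(data, splits, features,
                           contract = logistic_contract(),
                           id_col = "participant", label_col = "label") {
  y <- as.integer(data[[label_col]])
  per <- matrix(NA_real_, length(splits), 4,
                dimnames = list(NULL, c("accuracy", "precision", "recall", "auc")))
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    xtr <- data[sp$train_rows, features, drop = FALSE]
    attr(xtr, "groups") <- data[[id_col]][sp$train_rows]
    m <- contract$fit(xtr, y[sp$train_rows])
    p <- contract$predict_probability(m, data[sp$test_rows, features, drop = FALSE])
    if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
      stop("classifier contract violation: probabilities outside [0, 1]")
    }
    yt <- y[sp$test_rows]
    pred <- as.integer(p > 0.5)
    tp <- sum(pred == 1L & yt == 1L)
    per[s, "accuracy"] <- 100 * mean(pred == yt)
    per[s, "precision"] <- if (sum(pred == 1L)) 100 * tp / sum(pred == 1L) else NA_real_
    per[s, "recall"] <- 100 * tp / sum(yt == 1L)
    per[s, "auc"] <- auc(p, yt)
  }
  per <- as.data.frame(per)
  per$split <- seq_along(splits)
  structure(list(per_split = per,
                 aggregate = colMeans(per[, c("accuracy", "precision", "recall", "auc")],
                                      na.rm = TRUE),
                 cutoff = 0.5, n_splits = length(splits)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<eval_report> %d balanced splits (cutoff %.2f)\n", x$n_splits, x$cutoff))
  cat(sprintf("  accuracy %.1f%%  precision %.1f%%  recall %.1f%%  AUC %.3f\n",
              a["accuracy"], a["precision"], a["recall"], a["auc"]))
  invisible(x)
}
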