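#' Two-sample rank test for a shift between subgroups
#'
#' Independent-samples Mann-Whitney U test, two-sided. For combined sample
#' sizes up to \code{exact_max} the p-value is exact by enumeration of all
#' group labelings (valid under ties); above that, the tie-corrected normal
#' approximation is used. The statistic is \eqn{U = \sum ranks_1 - n_1(n_1+1)/2},
#' and the two-sided p is the probability of a U at least as far from its
#' null mean \eqn{n_1 n_2 / 2} as observed.
#'
#' @param g1,g2 numeric samples (typically per-participant mean sleep-quality
#'   scores), both non-empty.
#' @param exact_max largest combined n for exact enumeration, default 20.
#' @return List of class \code{rank_sum_test}: \code{statistic} (U for group
#'   1), \code{p_value}, \code{method}.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
rank_sum_test <- function(g1, g2, exact_max = 20L) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pooled <- c(g1, g2)
  r <- rank(pooled)
  u_of <- function(idx1) sum(r[idx1]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  dev_obs <- abs(u_obs - mu)
  if (n1 + n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    devs <- abs(apply(combos, 2, u_of) - mu)
    p <- mean(devs >= dev_obs - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    n <- n1 + n2
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- dev_obs / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "tie-corrected normal approximation"
  }
  structure(list(statistic = u_obs, p_value = p, method = method,
                 n1 = n1, n2 = n2),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$statistic, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Define a subgroup comparison
#'
#' @param name label for the comparison row.
#' @param predicate function of the participant table returning a logical
#'   vector; TRUE rows form group 2, FALSE rows group 1.
#' @param scope \code{"all"} (everyone) or \code{"MS"} (people with MS only
#'   form group 1's complement side).
#' @param group1,group2 display labels.
#' @return List of class \code{subgroup_spec}.
#' @export
subgroup_spec <- function(name, predicate, scope = c("all", "MS"),
                          group1 = "no", group2 = "yes") {
  scope <- match.arg(scope)
  structure(list(name = name, predicate = predicate, scope = scope,
                 group1 = group1, group2 = group2),
            class = "subgroup_spec")
}

#' The standard subgroup comparisons
#'
#' Sex, disease status and MS type, ANS dysfunction, spinal-cord
#' involvement, and the binarized disability scales, each emitted for the
#' whole cohort and (where meaningful) for the MS group alone.
#'
#' @return List of [subgroup_spec()]s.
#' @export
default_subgroup_specs <- function() {
  list(
    subgroup_spec("sex", function(p) p$sex == "M", "all", "female", "male"),
    subgroup_spec("disease status", function(p) p$group == "MS", "all",
                  "no MS", "MS"),
    subgroup_spec("ANS dysfunction: all", function(p) p$ans_dysfunction, "all",
                  "no ANS dysfunction", "ANS dysfunction"),
    subgroup_spec("ANS dysfunction: MS", function(p) p$ans_dysfunction, "MS",
                  "no ANS dysfunction", "ANS dysfunction"),
    subgroup_spec("spinal cord: all", function(p) p$spinal_cord, "all",
                  "unaffected", "affected"),
    subgroup_spec("spinal cord: MS", function(p) p$spinal_cord, "MS",
                  "unaffected", "affected"),
    subgroup_spec("MSSS: all", function(p) p$msss_severe, "all", "<=3", ">3"),
    subgroup_spec("MSSS: MS", function(p) p$msss_severe, "MS", "<=3", ">3"),
    subgroup_spec("ARMSS: all", function(p) p$armss_severe, "all", "<=4", ">4"),
    subgroup_spec("ARMSS: MS", function(p) p$armss_severe, "MS", "<=4", ">4"),
    subgroup_spec("EDSS: all", function(p) p$edss_severe, "all", "<=3", ">3"),
    subgroup_spec("EDSS: MS", function(p) p$edss_severe, "MS", "<=3", ">3"))
}

#' Subgroup comparison report of mean sleep quality
#'
#' Each participant is first reduced to their mean sleep-quality score over
#' the study (repeated nights of one person are not independent), then each
#' spec's two groups are compared with [rank_sum_test()]. Specs whose
#' predicate leaves a group empty are skipped with a warning.
#'
#' @param daily data.frame with \code{participant} and \code{sleep_quality}.
#' @param profiles participant table including binarized severity flags
#'   (see [binarize_static()]).
#' @param specs list of [subgroup_spec()]s, default
#'   [default_subgroup_specs()].
#' @return data.frame, one row per spec: group labels, sizes, means, SDs and
#'   the two-sided p-value.
#' @export
subgroup_report <- function(daily, profiles, specs = default_subgroup_specs()) {
  sq <- tapply(daily$sleep_quality, daily$participant, mean, na.rm = TRUE)
  profiles <- profiles[profiles$id %in% names(sq), , drop = FALSE]
  score <- as.numeric(sq[profiles$id])
  rows <- list()
  for (sp in specs) {
    base <- if (sp$scope == "MS") profiles$group == "MS" else rep(TRUE, nrow(profiles))
    flag <- sp$predicate(profiles)
    g2 <- flag & base
    g1 <- !flag & base
    if (!any(g1) || !any(g2)) {
      warning(sprintf("subgroup '%s': empty group, skipped", sp$name), call. = FALSE)
      next
    }
    ts <- rank_sum_test(score[g1], score[g2])
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = sp$name, scope = sp$scope,
      group1 = sp$group1, n1 = sum(g1),
      mean1 = mean(score[g1]), sd1 = stats::sd(score[g1]),
      group2 = sp$group2, n2 = sum(g2),
      mean2 = mean(score[g2]), sd2 = stats::sd(score[g2]),
      p_value = ts$p_value, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(comparison = character(0))
  rownames(out) <- NULL
  out
}

#' Pearson correlation matrices per group
#'
#' Pairwise-complete Pearson correlations with two-sided p-values from the t
#' transform \eqn{t = r \sqrt{(n-2)/(1-r^2)}}, computed separately per
#' group.
#'
#' @param features data.frame of numeric feature columns.
#' @param columns columns to correlate.
#' @param group optional per-row group labels; NULL treats all rows as one
#'   group.
#' @param min_pairs minimum paired observations per cell, default 3.
#' @return Named list per group: \code{r} and \code{p} matrices.
#' @export
correlation_matrix <- function(features, columns = names(features),
                               group = NULL, min_pairs = 3L) {
  columns <- intersect(columns, names(features))
  if (length(columns) < 2L) stop("need at least two columns to correlate")
  group <- group %||% rep("all", nrow(features))
  out <- list()
  for (g in unique(group)) {
    x <- as.matrix(features[group == g, columns, drop = FALSE])
    k <- length(columns)
    r <- p <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
    for (i in seq_len(k)) for (j in i:k) {
      ok <- stats::complete.cases(x[, c(i, j)])
      n <- sum(ok)
      if (n < min_pairs) next
      rij <- stats::cor(x[ok, i], x[ok, j])
      r[i, j] <- r[j, i] <- rij
      if (i == j) { p[i, j] <- 0; next }
      if (abs(rij) >= 1) { p[i, j] <- p[j, i] <- 0; next }
      tv <- rij * sqrt((n - 2) / (1 - rij^2))
      p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tv), df = n - 2)
    }
    out[[as.character(g)]] <- list(r = r, p = p)
  }
  out
}

#' Sample size for estimating a proportion to a given precision
#'
#' Smallest n such that the normal-approximation confidence half-width
#' \eqn{z_{(1+c)/2}\sqrt{p(1-p)/n}} does not exceed \code{halfwidth}. Used
#' at the study-design stage: estimating a compliance rate of 85% to within
#' plus/minus 10 percentage points at 95% confidence needs 49 participants.
#'
#' @param p expected proportion, in (0, 1).
#' @param halfwidth CI half-width, in (0, 1).
#' @param confidence confidence level, in (0, 1), default 0.95.
#' @return Minimal integer n.
#' @export
#' @examples
#' sample_size_for_proportion(0.85, 0.10, 0.95)  # 49
sample_size_for_proportion <- function(p, halfwidth, confidence = 0.95) {
  stopifnot_scalar(p, "p", 0, 1, strict_lo = TRUE, strict_hi = TRUE)
  stopifnot_scalar(halfwidth, "halfwidth", 0, 1, strict_lo = TRUE, strict_hi = TRUE)
  stopifnot_scalar(confidence, "confidence", 0, 1, strict_lo = TRUE, strict_hi = TRUE)
  if (halfwidth >= min(p, 1 - p)) {
    warning("half-width exceeds the distance of p to 0 or 1; the interval is uninformative on one side",
            call. = FALSE)
  }
  z <- stats::qnorm((1 + confidence) / 2)
  n <- ceiling(z^2 * p * (1 - p) / halfwidth^2)
  # guard against ceiling() landing one above the true minimum through
  # floating-point noise
  while (n > 1 && z * sqrt(p * (1 - p) / (n - 1)) <= halfwidth) n <- n - 1
  as.integer(n)
}
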