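# Independent oracles used to check the package's implementations.
# Each one deliberately takes a different route from the production code:
# explicit geometry, O(n^2) pair counting, exhaustive enumeration.

# Poincare descriptors via explicit point-to-line distances: project each
# consecutive pair (x_i, x_{i+1}) onto the 45-degree identity line and the
# -45-degree line through the centroid, and take population SDs of the
# signed distances.
oracle_poincare_geometric <- function(ibi) {
  n <- length(ibi)
  pts <- cbind(ibi[-n], ibi[-1L])
  # distance from point (a, b) to the line y = x, signed: (b - a)/sqrt(2)
  d1 <- (pts[, 2] - pts[, 1]) / sqrt(2)
  # distance to the -45-degree line through the centroid c: for line
  # x + y = const, signed distance is (a + b - const)/sqrt(2); the SD is
  # independent of const so use the centroid's value
  cst <- mean(pts[, 1] + pts[, 2])
  d2 <- (pts[, 1] + pts[, 2] - cst) / sqrt(2)
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  c(sd1 = psd(d1), sd2 = psd(d2), sdnn = psd(ibi))
}

# Brute-force detector rule: for every beat, the median of the surrounding
# window (computed with an explicit loop) and the quartile-deviation
# criterion, mirroring the documented rule independently of runmed().
oracle_detect <- function(ibi, mult = 3.32, k = 5L, floor_ms = 10) {
  n <- length(ibi)
  half <- k %/% 2L
  local_med <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::median(ibi[lo:hi])
  }, 0)
  qd <- stats::IQR(diff(ibi)) / 2
  abs(ibi - local_med) > mult * max(qd, floor_ms)
}

# AUC by explicit enumeration of all positive x negative pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p by brute-force permutation: recompute U for
# every labeling by direct pair counting (not via ranks)
oracle_ranksum_perm <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  u_pairs <- function(a, b) {
    tot <- 0
    for (x in a) for (y in b) {
      tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
    }
    tot
  }
  mu <- n1 * length(g2) / 2
  dev_obs <- abs(u_pairs(g1, g2) - mu)
  combos <- utils::combn(length(pooled), n1)
  devs <- apply(combos, 2, function(idx) {
    abs(u_pairs(pooled[idx], pooled[-idx]) - mu)
  })
  mean(devs >= dev_obs - 1e-12)
}

# small stream cohort shared by several signal-level tests (built once)
small_stream_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(
        simulate_cohort(sim_config(n_participants = 4, n_days = 3, seed = 402)))
    }
    cache
  }
})

# modelling-scale feature cohort, normalized, with label and usable columns
prep_model_data <- function(config) {
  co <- simulate_feature_cohort(config)
  norm <- suppressWarnings(normalize_per_participant(co$features))
  dat <- norm$data
  dat$label <- binarize_sleep_quality(dat$sleep_quality)
  cols <- scope_columns(setdiff(norm$columns, "sleep_quality"), "both")
  cols <- cols[colMeans(is.na(dat[, cols, drop = FALSE])) <= 0.5]
  cc <- stats::complete.cases(dat[, c(cols, "label")])
  list(cohort = co, norm = norm, dat = dat[cc, , drop = FALSE], cols = cols,
       lin = co$truth$lin[cc])
}
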