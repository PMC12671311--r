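# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population standard deviation
#'
#' Standard deviation with the n denominator, used for all windowed Poincare
#' descriptors (each 5-minute window is treated as a complete population of
#' beat pairs, not a sample from a longer stationary process).
#'
#' @param x numeric vector.
#' @return Non-negative scalar; 0 for length-1 input.
#' @keywords internal
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) stop("pop_sd: empty input")
  sqrt(sum((x - mean(x))^2) / n)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# user's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf,
                             strict_lo = FALSE, strict_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
  ok_lo <- if (strict_lo) x > lo else x >= lo
  ok_hi <- if (strict_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi) {
    stop(sprintf("'%s' = %g outside its valid range %s%g, %g%s", name, x,
                 if (strict_lo) "(" else "[", lo, hi,
                 if (strict_hi) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

# Rolling median smoother for 1 Hz streams; k forced odd, endpoints kept.
roll_med <- function(x, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  if (length(x) <= k) return(rep(stats::median(x), length(x)))
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

fmt_hm <- function(sec) {
  sec <- sec %% 86400
  sprintf("%02d:%02d", floor(sec / 3600), floor((sec %% 3600) / 60))
}
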