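new_cleaning_report <- function(n_input, kept_mask,
                                n_range = 0L, n_mavg = 0L, n_quot = 0L) {
  structure(list(n_input = n_input,
                 n_removed_range = n_range,
                 n_removed_moving_avg = n_mavg,
                 n_removed_quotient = n_quot,
                 kept_mask = kept_mask),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:", x$n_input, "beats in,",
      sum(x$kept_mask), "kept\n")
  cat(sprintf("  removed: range %d, moving-average %d, quotient %d\n",
              x$n_removed_range, x$n_removed_moving_avg,
              x$n_removed_quotient))
  invisible(x)
}

subset_series <- function(series, keep) {
  rr_series(series$intervals[keep], meta = series$meta)
}

#' Range filter for non-physiological intervals
#'
#' Discards intervals outside the physiological range. Boundaries are
#' inclusive: an interval exactly at a threshold survives. The defaults
#' 0.28 s and 2.4 s correspond to 214 bpm and 25 bpm (a commonly quoted
#' "50 bpm" equivalent for 2.4 s is arithmetically inconsistent; the
#' seconds values are authoritative here).
#'
#' @param series an [rr_series].
#' @param rr_min,rr_max thresholds in seconds, `0 < rr_min < rr_max`.
#' @return `list(series, report)` with the filtered [rr_series] and a
#'   `cleaning_report`.
#' @export
range_filter <- function(series, rr_min = 0.28, rr_max = 2.4) {
  stopifnot(inherits(series, "rr_series"))
  if (!(rr_min > 0 && rr_min < rr_max))
    stop("need 0 < rr_min < rr_max")
  keep <- series$intervals >= rr_min & series$intervals <= rr_max
  list(series = subset_series(series, keep),
       report = new_cleaning_report(length(keep), keep,
                                    n_range = sum(!keep)))
}

#' Moving-average filter for locally deviant intervals
#'
#' Removes beat `i` when it deviates from the mean of its window
#' neighbors (the central sample excluded, windows truncated at the
#' edges) by more than the threshold fraction. Defaults: a 21-sample
#' window (10 on each side) and 20%.
#'
#' @param series an [rr_series].
#' @param window odd window size in beats (>= 3).
#' @param threshold relative deviation triggering removal, in (0, 1).
#' @return `list(series, report)`.
#' @export
moving_average_filter <- function(series, window = 21, threshold = 0.2) {
  stopifnot(inherits(series, "rr_series"))
  if (window < 3 || window %% 2 != 1) stop("window must be odd and >= 3")
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  x <- series$intervals
  n <- length(x)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  local_mean <- (cs[hi + 1] - cs[lo] - x) / (hi - lo)
  keep <- abs(x - local_mean) / local_mean <= threshold
  list(series = subset_series(series, keep),
       report = new_cleaning_report(n, keep, n_mavg = sum(!keep)))
}

#' Quotient filter for abrupt beat-to-beat jumps
#'
#' Removes beat `i` when its ratio to the previous or the next interval
#' falls outside `[1 - t, 1 + t]`. All beats are judged against their
#' original (pre-removal) neighbors in a single pass, so the result does
#' not depend on processing order; endpoint beats have only one
#' neighbor.
#'
#' @param series an [rr_series] of at least 3 beats.
#' @param threshold tolerated relative change, in (0, 1); default 20%.
#' @return `list(series, report)`.
#' @export
quotient_filter <- function(series, threshold = 0.2) {
  stopifnot(inherits(series, "rr_series"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  x <- series$intervals
  n <- length(x)
  if (n < 3) stop("quotient filter needs at least 3 beats")
  bad_ratio <- function(r) !is.na(r) & (r < 1 - threshold | r > 1 + threshold)
  r_prev <- c(NA, x[-1] / x[-n])
  r_next <- c(x[-n] / x[-1], NA)
  keep <- !(bad_ratio(r_prev) | bad_ratio(r_next))
  list(series = subset_series(series, keep),
       report = new_cleaning_report(n, keep, n_quot = sum(!keep)))
}

#' Full cleaning pipeline
#'
#' Applies the three non-physiological-beat removal techniques in order:
#' range filter, moving-average filter, quotient filter. Removed beats
#' are deleted and the tachogram re-indexed (gaps closed); beat times
#' are recomputed from the surviving intervals.
#'
#' @param series an [rr_series].
#' @param config configuration list supplying the default thresholds.
#' @param min_beats minimum surviving length; shorter output raises an
#'   "insufficient data" error (spectral and entropy stages need
#'   length).
#' @return `list(series, report)`; the report's `kept_mask` refers to
#'   the input beats and its removal counts sum consistently.
#' @export
preprocess_pipeline <- function(series, config = sanclock_defaults(),
                                min_beats = 64) {
  stopifnot(inherits(series, "rr_series"))
  cl <- config$cleaning
  s1 <- range_filter(series, cl$rr_min, cl$rr_max)
  s2 <- moving_average_filter(s1$series, cl$ma_window, cl$ma_threshold)
  s3 <- quotient_filter(s2$series, cl$quotient_threshold)
  # map the stage masks back onto the original beat indices
  keep <- s1$report$kept_mask
  idx1 <- which(keep)
  keep[idx1[!s2$report$kept_mask]] <- FALSE
  idx2 <- idx1[s2$report$kept_mask]
  keep[idx2[!s3$report$kept_mask]] <- FALSE
  rep <- new_cleaning_report(length(series$intervals), keep,
                             n_range = s1$report$n_removed_range,
                             n_mavg = s2$report$n_removed_moving_avg,
                             n_quot = s3$report$n_removed_quotient)
  if (sum(keep) < min_beats)
    stop("insufficient data: fewer than ", min_beats,
         " beats survive cleaning")
  list(series = s3$series, report = rep)
}
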