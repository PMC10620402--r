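#' Time-domain and Poincare beat-interval variability metrics
#'
#' Computes the standard short-term variability panel: AVNN (mean beat
#' interval), SDNN (standard deviation of intervals), RMSSD (root mean
#' square of successive differences), pNN50 (percentage of successive
#' differences exceeding 50 ms, strict), and the Poincare descriptors
#' SD1 and SD2. All values are reported in ms (pNN50 in percent).
#'
#' Variance convention: population (divide by n) throughout, so that the
#' Poincare identity `SD1 = RMSSD / sqrt(2)` holds exactly (successive
#' differences are treated as zero-mean).
#'
#' @param series an [rr_series] of at least 2 beats (3 for the
#'   difference-based metrics).
#' @return A `biv_report` list with fields `avnn`, `sdnn`, `rmssd`,
#'   `pnn50`, `sd1`, `sd2`, `n_beats`.
#' @export
time_domain_metrics <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  rr <- 1000 * series$intervals
  n <- length(rr)
  if (n < 2) stop("at least 2 beats are required")
  avnn <- mean(rr)
  sdnn <- sqrt(mean((rr - avnn)^2))
  if (n >= 3) {
    d <- diff(rr)
    rmssd <- sqrt(mean(d^2))
    pnn50 <- 100 * mean(abs(d) > 50)
  } else {
    rmssd <- pnn50 <- NA_real_
  }
  pc <- poincare_from(rr)
  structure(list(avnn = avnn, sdnn = sdnn, rmssd = rmssd, pnn50 = pnn50,
                 sd1 = pc[1], sd2 = pc[2], n_beats = n),
            class = "biv_report")
}

poincare_from <- function(rr) {
  if (length(rr) < 3) return(c(NA_real_, NA_real_))
  d <- diff(rr)
  sd1 <- sqrt(mean(d^2) / 2)
  sdnn <- sqrt(mean((rr - mean(rr))^2))
  s2sq <- 2 * sdnn^2 - sd1^2
  if (s2sq < 0) {
    warning("degenerate alternating series: SD2 reported as 0")
    s2sq <- 0
  }
  c(sd1, sqrt(s2sq))
}

#' Poincare-plot descriptors SD1 and SD2
#'
#' SD1 (short-term variability) is the dispersion perpendicular to the
#' identity line of the lagged scatter plot, `sqrt(Var(diff(RR)) / 2)`;
#' SD2 (long-term) is `sqrt(2 * SDNN^2 - SD1^2)`. Population variance
#' convention; successive differences treated as zero-mean, making
#' `SD1 = RMSSD / sqrt(2)` an exact identity.
#'
#' @param series an [rr_series] of at least 3 beats.
#' @return Named numeric vector `c(sd1, sd2)` in ms.
#' @export
poincare <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  if (length(series$intervals) < 3) stop("at least 3 beats are required")
  p <- poincare_from(1000 * series$intervals)
  c(sd1 = p[1], sd2 = p[2])
}

#' @export
print.biv_report <- function(x, ...) {
  cat(sprintf(
    "BIV report (%d beats): AVNN %.1f ms, SDNN %.2f ms, RMSSD %.2f ms,\n",
    x$n_beats, x$avnn, x$sdnn, x$rmssd))
  cat(sprintf("  pNN50 %.1f%%, SD1 %.2f ms, SD2 %.2f ms\n",
              x$pnn50, x$sd1, x$sd2))
  invisible(x)
}

#' Per-recording metric table for a cohort
#'
#' @param cohort an `rr_cohort` (see [generate_cohort()]) or any list of
#'   records with `subject_id`, `age`, `group`, `state` and `series`.
#' @param clean apply [preprocess_pipeline()] before measuring.
#' @param config configuration list.
#' @return A data frame with one row per subject and state, columns as
#'   in the BIV report. Suitable for [utils::write.csv()].
#' @export
biv_table <- function(cohort, clean = TRUE, config = sanclock_defaults()) {
  rows <- lapply(cohort, function(rec) {
    s <- rec$series
    if (clean) s <- preprocess_pipeline(s, config)$series
    m <- time_domain_metrics(s)
    data.frame(subject_id = rec$subject_id %||% NA,
               age = rec$age %||% NA,
               group = rec$group %||% s$meta$group %||% NA,
               state = rec$state %||% s$meta$state %||% NA,
               avnn = m$avnn, sdnn = m$sdnn, rmssd = m$rmssd,
               pnn50 = m$pnn50, sd1 = m$sd1, sd2 = m$sd2,
               n_beats = m$n_beats, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
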