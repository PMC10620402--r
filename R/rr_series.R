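#' Construct an RR-interval series
#'
#' The basic container of the package: an ordered sequence of beat
#' intervals (seconds) with cumulative beat times and subject metadata.
#'
#' @param intervals numeric vector of beat intervals in seconds; all > 0.
#' @param meta named list of subject metadata. Recognised fields:
#'   `subject_id`, `age` (years), `group` (`"young"` or `"adult"`) and
#'   `state` (`"BSL"`, `"Anesthesia"` or `"ABK"`).
#' @param beat_times optional beat-time vector (seconds), strictly
#'   increasing and the same length as `intervals`. Defaults to the
#'   cumulative sum of the intervals (first beat at its own interval).
#'   A filtered series read back at its original beat times may carry
#'   beat times that are not the cumulative sums of its intervals.
#'
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(intervals, meta = list(), beat_times = NULL) {
  intervals <- as.numeric(intervals)
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("all RR intervals must be finite and positive")
  if (is.null(beat_times)) beat_times <- cumsum(intervals)
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) != length(intervals))
    stop("beat_times must match intervals in length")
  if (any(diff(beat_times) <= 0))
    stop("beat_times must be strictly increasing")
  structure(list(intervals = intervals, beat_times = beat_times,
                 meta = meta),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  m <- x$meta
  if (length(x$intervals) == 0L) {
    cat("RR-interval series: 0 beats\n")
    return(invisible(x))
  }
  cat("RR-interval series:", length(x$intervals), "beats,",
      sprintf("%.1f s", x$beat_times[length(x$beat_times)] - x$beat_times[1]),
      "\n")
  cat(sprintf("  mean RR %.1f ms, SDNN %.1f ms\n",
              1000 * mean(x$intervals), 1000 * stats::sd(x$intervals)))
  if (length(m)) {
    lab <- paste(vapply(names(m), function(k) paste0(k, "=", m[[k]]),
                        character(1)), collapse = ", ")
    cat("  meta:", lab, "\n")
  }
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Intervalogram plot of an RR series
#'
#' @param x an [rr_series] object.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.rr_series <- function(x, ...) {
  graphics::plot(x$beat_times, 1000 * x$intervals, type = "l",
                 xlab = "time (s)", ylab = "RR (ms)", ...)
  invisible(x)
}

#' @export
as.data.frame.rr_series <- function(x, ...) {
  m <- x$meta
  data.frame(beat_time_s = x$beat_times, rr_s = x$intervals,
             subject_id = if (is.null(m$subject_id)) NA else m$subject_id,
             age = if (is.null(m$age)) NA else m$age,
             group = if (is.null(m$group)) NA else m$group,
             state = if (is.null(m$state)) NA else m$state,
             stringsAsFactors = FALSE)
}

#' Read and write RR series
#'
#' Two plain-text formats are supported: a one-interval-per-line file
#' (seconds) and a CSV with columns `beat_time_s`, `rr_s`, `subject_id`,
#' `age`, `group`, `state`.
#'
#' @param path file path.
#' @param format `"txt"` or `"csv"`; inferred from the extension when
#'   missing.
#' @return `read_rr` returns an [rr_series]; `write_rr` returns `path`
#'   invisibly.
#' @export
read_rr <- function(path, format = c("auto", "txt", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  if (format == "txt") {
    iv <- scan(path, what = numeric(), quiet = TRUE)
    return(rr_series(iv))
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- list()
  for (k in c("subject_id", "age", "group", "state"))
    if (k %in% names(d) && !all(is.na(d[[k]]))) meta[[k]] <- d[[k]][1]
  rr_series(d$rr_s, meta = meta,
            beat_times = if ("beat_time_s" %in% names(d)) d$beat_time_s)
}

#' @param series an [rr_series] object.
#' @rdname read_rr
#' @export
write_rr <- function(series, path, format = c("auto", "txt", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  if (format == "txt") {
    writeLines(formatC(series$intervals, format = "fg", digits = 9), path)
  } else {
    utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  }
  invisible(path)
}
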