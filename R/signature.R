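#' Specify a signature band-stop filter
#'
#' A signature filter is a linear-phase FIR band-stop filter on the RR
#' tachogram that removes the spectral contribution of one control
#' system (autonomic bands, or the bands altered by anesthesia), so that
#' a basal recording can emulate a pharmacological state. Filters carry
#' one stop band (order 100, Blackman window of 101 taps) or two (order
#' 150, 151 taps), following the published design.
#'
#' @param stop_bands list of one or two `c(low, high)` stop bands in Hz;
#'   an empty list gives a pass-through filter.
#' @param order FIR order (taps - 1). Defaults to 100 for mono-band and
#'   150 for dual-band filters.
#' @param target optional `c(age_group, emulated_state)` label.
#' @return A `signature_spec` object.
#' @export
signature_spec <- function(stop_bands, order = NULL, target = NULL) {
  stop_bands <- lapply(stop_bands, as.numeric)
  if (length(stop_bands) > 2)
    stop("at most two stop bands are supported")
  for (b in stop_bands) {
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1])
      stop("each stop band must be c(low, high) with 0 < low < high")
  }
  if (length(stop_bands) == 2) {
    o <- order(vapply(stop_bands, `[`, numeric(1), 1))
    stop_bands <- stop_bands[o]
    if (stop_bands[[1]][2] >= stop_bands[[2]][1])
      stop("dual stop bands must be disjoint")
  }
  if (is.null(order))
    order <- if (length(stop_bands) <= 1) 100L else 150L
  order <- as.integer(order)
  if (order < 2 || order %% 2 != 0)
    stop("filter order must be a positive even integer")
  structure(list(stop_bands = stop_bands, order = order,
                 window = "blackman", window_length = order + 1L,
                 target = target),
            class = "signature_spec")
}

#' @export
print.signature_spec <- function(x, ...) {
  kind <- if (length(x$stop_bands) == 0) "pass-through"
          else if (length(x$stop_bands) == 1) "mono-band" else "dual-band"
  cat("Signature filter (", kind, "), order ", x$order,
      ", Blackman window of ", x$window_length, "\n", sep = "")
  for (b in x$stop_bands)
    cat(sprintf("  stop band %.4g-%.4g Hz\n", b[1], b[2]))
  if (!is.null(x$target))
    cat("  target:", paste(x$target, collapse = " / "), "\n")
  invisible(x)
}

#' Built-in signature-filter presets
#'
#' The four published filters, keyed by age group and emulated state:
#' * `young-anesthesia`: dual stop bands 0.013-0.03 Hz (part of VLF) and
#'   0.046-0.158 Hz (all of LF), applied to basal recordings.
#' * `adult-anesthesia`: mono stop band 0.03-0.2 Hz, applied to basal
#'   recordings.
#' * `young-abk`: mono stop band 0.05-0.58 Hz (most of LF and nearly all
#'   HF), applied to anesthesia recordings.
#' * `adult-abk`: dual stop bands 0.015-0.14 Hz and 0.16-0.58 Hz,
#'   applied to basal recordings.
#'
#' @param config configuration list, see [sanclock_defaults()].
#' @return Named list of [signature_spec] objects; each carries
#'   `source_state` and `target_state` attributes describing which state
#'   it consumes and which it emulates.
#' @export
signature_presets <- function(config = sanclock_defaults()) {
  out <- lapply(names(config$presets), function(nm) {
    p <- config$presets[[nm]]
    grp <- sub("-.*$", "", nm)
    spec <- signature_spec(p$stop_bands,
                           target = c(grp, p$target_state))
    attr(spec, "source_state") <- p$source_state
    attr(spec, "target_state") <- p$target_state
    spec
  })
  stats::setNames(out, names(config$presets))
}

#' Design windowed-sinc band-stop filter taps
#'
#' Builds linear-phase FIR band-stop coefficients by subtracting ideal
#' band-pass impulse responses from a unit impulse, tapering with a
#' Blackman window and normalizing the DC gain to exactly one. With no
#' stop bands the result is a unit impulse (pass-through).
#'
#' @param spec a [signature_spec].
#' @param fs sampling rate of the processing grid in Hz.
#' @return Numeric vector of `order + 1` taps with attributes `fs` and
#'   `spec`.
#' @export
design_bandstop <- function(spec, fs = 4) {
  stopifnot(inherits(spec, "signature_spec"))
  for (b in spec$stop_bands)
    if (b[2] >= fs / 2) stop("stop-band edge at or above Nyquist")
  n <- spec$order
  k <- seq(0, n) - n / 2
  h <- ifelse(k == 0, 1, 0)
  for (b in spec$stop_bands) {
    f1 <- b[1] / fs
    f2 <- b[2] / fs
    bp <- ifelse(k == 0, 2 * (f2 - f1),
                 (sin(2 * pi * f2 * k) - sin(2 * pi * f1 * k)) / (pi * k))
    h <- h - bp
  }
  w <- as.numeric(signal::blackman(n + 1))
  h <- h * w
  # normalize to exactly unit DC gain, the fir1-style convention. For
  # stop bands much narrower than the taper's transition width the
  # windowed notch leaks towards DC, so this normalization leaves the
  # passband above the bands carrying a gain surplus; all downstream
  # analyses (MSE, normalized band powers) are insensitive to scale.
  h <- h / sum(h)
  attr(h, "fs") <- fs
  attr(h, "spec") <- spec
  h
}

#' Frequency response magnitude of FIR taps
#'
#' @param taps FIR coefficient vector.
#' @param freqs frequencies in Hz at which to evaluate.
#' @param fs sampling rate in Hz (defaults to the `fs` attribute of
#'   `taps`).
#' @return Magnitude response at `freqs`.
#' @export
fir_response <- function(taps, freqs, fs = attr(taps, "fs")) {
  if (is.null(fs)) stop("fs is required")
  k <- seq_along(taps) - 1
  vapply(freqs, function(f)
    Mod(sum(taps * exp(-2i * pi * f * k / fs))), numeric(1))
}

# Zero-phase (forward-backward) filtering with reflection padding.
# Equivalent to centered convolution with conv(b, rev(b)); the effective
# magnitude response is |H(f)|^2.
zero_phase_filter <- function(x, taps) {
  bb <- convolve(taps, rev(taps), type = "open")
  half <- (length(bb) - 1) / 2
  npad <- length(bb)
  if (length(x) <= npad)
    stop("series too short for stable zero-phase filtering")
  xpad <- c(2 * x[1] - rev(x[2:(npad + 1)]),
            x,
            2 * x[length(x)] - rev(x[(length(x) - npad):(length(x) - 1)]))
  y <- stats::filter(xpad, bb, method = "convolution", sides = 2)
  as.numeric(y[(npad + 1):(npad + length(x))])
}

# Resample a tachogram (ms at beat times) onto a uniform grid.
resample_tachogram <- function(series, fs) {
  bt <- series$beat_times
  t_grid <- seq(bt[1], bt[length(bt)], by = 1 / fs)
  x <- stats::spline(bt, 1000 * series$intervals, xout = t_grid,
                     method = "fmm")$y
  list(t = t_grid, x = x)
}

#' Apply a signature filter to an RR series
#'
#' The tachogram is resampled to a uniform grid (cubic interpolation),
#' its mean removed, filtered forward-backward with the band-stop taps
#' (zero phase, attenuation applied twice), the mean restored and the
#' result read back at the original beat times. The output has the same
#' beat count and beat times as the input and an unchanged mean beat
#' interval.
#'
#' @param series a cleaned [rr_series].
#' @param spec a [signature_spec], or the name of a built-in preset
#'   (see [signature_presets()]).
#' @param fs processing-grid rate in Hz. The default 4 Hz grid is one
#'   convention for giving the beat-indexed series a time base;
#'   `mode = "beat"` instead filters the beat-indexed series directly at
#'   an effective rate of one over the mean beat interval.
#' @param mode `"uniform"` (resample to `fs`) or `"beat"`.
#' @param config configuration list used to resolve preset names.
#' @return A filtered [rr_series].
#' @export
apply_signature <- function(series, spec, fs = 4,
                            mode = c("uniform", "beat"),
                            config = sanclock_defaults()) {
  stopifnot(inherits(series, "rr_series"))
  mode <- match.arg(mode)
  if (is.character(spec)) {
    presets <- signature_presets(config)
    if (!spec %in% names(presets)) stop("unknown preset: ", spec)
    spec <- presets[[spec]]
  }
  if (length(spec$stop_bands) == 0) return(series)
  if (mode == "beat") {
    fs <- 1 / mean(series$intervals)
    x <- 1000 * series$intervals
    taps <- design_bandstop(spec, fs = fs)
    mu <- mean(x)
    y <- zero_phase_filter(x - mu, taps) + mu
    return(rr_series(pmax(y, 1) / 1000, meta = series$meta,
                     beat_times = series$beat_times))
  }
  taps <- design_bandstop(spec, fs = fs)
  g <- resample_tachogram(series, fs)
  if (length(g$x) < 10 * spec$order)
    stop("series too short for stable filtering at this order")
  mu <- mean(g$x)
  y <- zero_phase_filter(g$x - mu, taps) + mu
  rr_new <- stats::spline(g$t, y, xout = series$beat_times,
                          method = "fmm")$y
  rr_series(pmax(rr_new, 1) / 1000, meta = series$meta,
            beat_times = series$beat_times)
}

#' Tune signature stop bands by grid search
#'
#' Exhaustively searches a grid of candidate stop-band sets, scoring
#' each by the mean per-scale multiscale-entropy p-value between the
#' filtered source series and the target-state series of the training
#' pairs (higher means the filtered series are statistically
#' indistinguishable from the target state). Deterministic: ties go to
#' the earliest candidate in grid order.
#'
#' @param train list of `list(source = rr_series, target = rr_series)`
#'   pairs (matched subjects).
#' @param initial a [signature_spec] providing order/window defaults.
#' @param grid list of candidate `stop_bands` values (each a list of
#'   `c(low, high)` bands; an empty list means no filtering).
#' @param fs processing-grid rate in Hz.
#' @param mse_args list of arguments for [multiscale_entropy()].
#' @return The winning [signature_spec], with attributes `mean_p`
#'   (its score) and `scores` (all candidate scores).
#' @export
tune_filter <- function(train, initial, grid, fs = 4,
                        mse_args = list(S = 20, m = 2, r_fraction = 0.2)) {
  if (length(train) < 2) stop("at least 2 training pairs are required")
  if (length(grid) == 0) stop("empty candidate grid")
  target_curves <- lapply(train, function(p)
    do.call(multiscale_entropy, c(list(p$target), mse_args)))
  scores <- vapply(grid, function(bands) {
    spec_i <- signature_spec(bands, target = initial$target)
    filt_curves <- lapply(train, function(p) {
      f <- if (length(bands) == 0) p$source
           else apply_signature(p$source, spec_i, fs = fs)
      do.call(multiscale_entropy, c(list(f), mse_args))
    })
    sim <- mse_similarity(filt_curves, target_curves, paired = TRUE)
    if (is.na(sim$mean_p)) -Inf else sim$mean_p
  }, numeric(1))
  best <- which.max(scores)   # first max wins
  out <- signature_spec(grid[[best]], target = initial$target)
  attr(out, "mean_p") <- scores[best]
  attr(out, "scores") <- scores
  out
}
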