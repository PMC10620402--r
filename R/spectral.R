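#' Power spectral density of an RR tachogram
#'
#' Two estimators are provided. `"welch"` cubic-interpolates the
#' tachogram onto a uniform grid (default 4 Hz), removes the mean, and
#' averages modified periodograms over Hamming-windowed segments of
#' 256 s with 50% overlap (shorter recordings fall back to a single
#' full-length segment). `"lomb"` evaluates the Lomb-Scargle
#' periodogram directly on the unevenly sampled beat times (no
#' resampling), normalized so the periodogram integrates to the
#' tachogram variance. Units are ms^2/Hz throughout.
#'
#' @param series an [rr_series] of at least 64 beats.
#' @param method `"welch"` or `"lomb"`.
#' @param resample_hz uniform grid rate for the Welch estimator; must
#'   exceed twice the highest band edge of interest.
#' @param segment_s Welch segment length in seconds.
#' @param fmax_lomb highest frequency (Hz) evaluated by the Lomb
#'   estimator.
#' @return A `spectral_result` with `freqs` (Hz) and `psd` (ms^2/Hz);
#'   band powers are added by [band_powers()].
#' @export
compute_psd <- function(series, method = c("welch", "lomb"),
                        resample_hz = 4, segment_s = 256,
                        fmax_lomb = 0.65) {
  stopifnot(inherits(series, "rr_series"))
  method <- match.arg(method)
  if (length(series$intervals) < 64)
    stop("at least 64 beats are required for spectral analysis")
  if (method == "welch") {
    g <- resample_tachogram(series, resample_hz)
    out <- welch_psd(g$x - mean(g$x), fs = resample_hz,
                     nseg = round(segment_s * resample_hz))
  } else {
    x <- 1000 * series$intervals
    t <- series$beat_times
    dur <- t[length(t)] - t[1]
    df <- 1 / (2 * dur)     # 2x oversampled frequency grid
    freqs <- seq(df, fmax_lomb, by = df)
    p <- lomb_periodogram(t, x - mean(x), freqs)
    # normalize to a density whose integral equals the variance
    p <- p * stats::var(x) / (sum(p) * df)
    out <- list(freqs = freqs, psd = p)
  }
  structure(list(freqs = out$freqs, psd = out$psd, method = method),
            class = "spectral_result")
}

# Welch's averaged modified periodogram (one-sided), x demeaned.
welch_psd <- function(x, fs, nseg, overlap = 0.5) {
  n <- length(x)
  nseg <- min(nseg, n)
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, n - nseg + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  scale <- fs * sum(w^2)
  nh <- nseg %/% 2
  acc <- numeric(nh + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)] * w
    X <- stats::fft(seg)
    pxx <- Mod(X[1:(nh + 1)])^2 / scale
    pxx[2:(nh + 1 - (nseg %% 2 == 0))] <-
      2 * pxx[2:(nh + 1 - (nseg %% 2 == 0))]
    acc <- acc + pxx
  }
  list(freqs = seq(0, nh) * fs / nseg, psd = acc / length(starts))
}

# Classical Lomb-Scargle periodogram at the given frequencies.
lomb_periodogram <- function(t, x, freqs) {
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1))
}

#' Integrate band powers from a PSD
#'
#' Absolute band powers are trapezoidal integrals of the PSD over the
#' VLF, LF and HF bands; normalized powers divide by their sum, so they
#' always add to one. `total_power` integrates the full resolved range.
#'
#' @param spec a `spectral_result` from [compute_psd()].
#' @param scheme a [band_scheme()] (or one of its names).
#' @param config configuration list used to resolve scheme names.
#' @return The `spectral_result` augmented with `band_power_abs`,
#'   `band_power_norm` (named VLF/LF/HF) and `total_power` (ms^2).
#' @export
band_powers <- function(spec, scheme = "standard",
                        config = sanclock_defaults()) {
  stopifnot(inherits(spec, "spectral_result"))
  if (is.character(scheme)) scheme <- band_scheme(scheme, config)
  if (max(unlist(scheme)) > max(spec$freqs))
    stop("band edges outside the resolved frequency range")
  pow <- vapply(c(vlf = "vlf", lf = "lf", hf = "hf"), function(nm) {
    e <- scheme[[nm]]
    trapz_band(spec$freqs, spec$psd, e[1], e[2])
  }, numeric(1))
  names(pow) <- c("VLF", "LF", "HF")
  spec$band_power_abs <- pow
  spec$band_power_norm <- if (sum(pow) > 0) pow / sum(pow) else pow * NA
  spec$total_power <- trapz_band(spec$freqs, spec$psd,
                                 min(spec$freqs), max(spec$freqs))
  spec$scheme <- scheme
  spec
}

trapz_band <- function(f, p, lo, hi) {
  sel <- f >= lo & f <= hi
  if (sum(sel) < 2) return(0)
  fx <- f[sel]
  px <- p[sel]
  sum(diff(fx) * (head(px, -1) + tail(px, -1)) / 2)
}

#' @export
print.spectral_result <- function(x, ...) {
  cat("PSD (", x$method, " estimator), ", length(x$freqs),
      " frequencies up to ", sprintf("%.3g", max(x$freqs)), " Hz\n",
      sep = "")
  if (!is.null(x$band_power_abs)) {
    cat(sprintf("  total power %.4g ms^2\n", x$total_power))
    for (nm in names(x$band_power_abs))
      cat(sprintf("  %s: %.4g ms^2 (%.1f%%)\n", nm,
                  x$band_power_abs[[nm]],
                  100 * x$band_power_norm[[nm]]))
  }
  invisible(x)
}

#' @export
plot.spectral_result <- function(x, log = "y", ...) {
  sel <- x$freqs > 0 & x$psd > 0
  graphics::plot(x$freqs[sel], x$psd[sel], type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "PSD (ms²/Hz)", ...)
  if (!is.null(x$scheme))
    graphics::abline(v = unlist(x$scheme), lty = 3)
  invisible(x)
}
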