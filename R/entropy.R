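#' Coarse-grain a series for multiscale entropy
#'
#' Averages the series over non-overlapping windows of `scale` beats;
#' the trailing remainder is dropped (output length `floor(n / scale)`).
#'
#' @param series an [rr_series] or numeric vector.
#' @param scale integer window length, >= 1. Scale 1 is the identity.
#' @return Numeric vector of window means.
#' @export
coarse_grain <- function(series, scale) {
  x <- if (inherits(series, "rr_series")) series$intervals else series
  scale <- as.integer(scale)
  if (scale < 1) stop("scale must be >= 1")
  nw <- length(x) %/% scale
  if (nw < 1) stop("series too short for requested scale")
  if (scale == 1L) return(as.numeric(x))
  colMeans(matrix(x[seq_len(nw * scale)], nrow = scale))
}

#' Sample entropy of a sequence
#'
#' `-ln(A / B)`, where `B` counts pairs of length-`m` templates matching
#' within tolerance `r` (Chebyshev distance, self-matches excluded) and
#' `A` counts the same pairs still matching at length `m + 1`. When
#' either count is zero the entropy is undefined and `NA` is returned
#' (with attribute `undefined = TRUE`) rather than an error.
#'
#' @param x numeric sequence of length >= m + 2.
#' @param m template length.
#' @param r tolerance, in the units of `x` (> 0).
#' @return Sample entropy value, or `NA` if undefined.
#' @export
sample_entropy <- function(x, m = 2, r) {
  x <- as.numeric(x)
  if (length(x) < m + 2) stop("sequence too short for template length m")
  if (r <= 0) stop("tolerance r must be positive")
  cnt <- sampen_counts_cpp(x, as.integer(m), r)
  if (cnt[1] == 0 || cnt[2] == 0)
    return(structure(NA_real_, undefined = TRUE))
  -log(cnt[1] / cnt[2])
}

#' Multiscale entropy of an RR series
#'
#' Sample entropy of progressively coarse-grained copies of the series
#' at scales `1..S`. The tolerance is fixed once as
#' `r_fraction * SD(original series)` and reused at every scale (Costa
#' convention), so the curve is invariant to adding a constant to all
#' intervals and to jointly rescaling intervals and tolerance.
#'
#' @param series an [rr_series] or numeric vector (ms recommended).
#' @param S maximum scale (default 20).
#' @param m template length (default 2).
#' @param r_fraction tolerance as a fraction of the series SD (default
#'   0.2).
#' @return An `mse_curve`: data frame with columns `scale` and `sampen`
#'   and attributes `m`, `r` (ms) and `r_rule`. Scales too short to
#'   estimate are truncated with a warning.
#' @export
multiscale_entropy <- function(series, S = 20, m = 2, r_fraction = 0.2) {
  x <- if (inherits(series, "rr_series")) 1000 * series$intervals
       else as.numeric(series)
  r <- r_fraction * stats::sd(x)
  if (r == 0) r <- .Machine$double.eps   # constant series: everything matches
  scales <- seq_len(S)
  usable <- scales[length(x) %/% scales >= m + 2]
  if (length(usable) < S)
    warning("series too short for scales above ", max(usable),
            "; curve truncated")
  vals <- vapply(usable, function(s)
    as.numeric(sample_entropy(coarse_grain(x, s), m = m, r = r)),
    numeric(1))
  structure(data.frame(scale = usable, sampen = vals),
            m = m, r = r,
            r_rule = sprintf("%.2f * SD of the scale-1 series", r_fraction),
            class = c("mse_curve", "data.frame"))
}

#' @export
plot.mse_curve <- function(x, ...) {
  graphics::plot(x$scale, x$sampen, type = "b", xlab = "scale",
                 ylab = "sample entropy", ...)
  invisible(x)
}

#' Average entropy over a scale range
#'
#' Undefined (NA) scales are excluded rather than imputed.
#'
#' @param curve an `mse_curve`.
#' @param scales integer vector of scales to average over.
#' @return Mean sample entropy over the defined requested scales.
#' @export
mse_band_mean <- function(curve, scales) {
  v <- curve$sampen[curve$scale %in% scales]
  mean(v, na.rm = TRUE)
}
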