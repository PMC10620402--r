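# Target one-sided PSD (ms^2/Hz) of the within-subject tachogram
# fluctuation on the uniform grid, for one state. Components: a 1/f
# (spectral exponent -1) fractal term, flat plateaus over the VLF/LF/HF
# bands, and a narrow respiratory peak inside HF. Non-basal states are
# shaped by the squared two-pass response of their signature filters
# (spectral nesting), then rescaled to the state's total SD.
state_psd <- function(params, freqs, config = sanclock_defaults()) {
  S <- numeric(length(freqs))
  rng <- params$one_over_f_range %||% c(0.0033, 0.5)
  f_lo <- rng[1]
  f_hi <- rng[2]
  if (params$one_over_f_amp > 0) {
    sel <- freqs >= f_lo & freqs <= f_hi
    S[sel] <- S[sel] + params$one_over_f_amp^2 / log(f_hi / f_lo) / freqs[sel]
  }
  bands <- band_scheme("standard", config)
  for (nm in c("VLF", "LF", "HF")) {
    a <- params$band_amp[[nm]]
    if (is.null(a) || a == 0) next
    e <- params[[paste0(tolower(nm), "_plateau")]] %||% bands[[tolower(nm)]]
    sel <- freqs >= e[1] & freqs < e[2]
    if (any(sel)) S[sel] <- S[sel] + a^2 / (e[2] - e[1])
  }
  rp <- params$resp_peak
  if (!is.null(rp) && rp$amp > 0)
    S <- S + rp$amp^2 * stats::dnorm(freqs, rp$freq, rp$width)
  # slow (humoral / thermoregulatory) oscillation deep in the VLF band
  sp <- params$slow_peak
  if (!is.null(sp) && sp$amp > 0)
    S <- S + sp$amp^2 * stats::dnorm(freqs, sp$freq, sp$width)
  # beat-level stochasticity (pacemaker firing noise / R-peak jitter):
  # a flat band above the HRV bands, surviving coarse state filtering
  ja <- params$jitter_amp %||% 0
  if (ja > 0) {
    sel <- freqs >= 0.5
    S[sel] <- S[sel] + ja^2 / (max(freqs) - 0.5)
  }
  if (length(params$shape)) {
    presets <- signature_presets(config)
    for (nm in params$shape) {
      taps <- design_bandstop(presets[[nm]], fs = config$grid_fs)
      S <- S * fir_response(taps, freqs)^4   # two zero-phase passes
    }
  }
  df <- freqs[2] - freqs[1]
  tot <- sum(S) * df
  if (!is.null(params$total_sd) && tot > 0)
    S <- S * params$total_sd^2 / tot
  S
}

# Gaussian surrogate with a prescribed one-sided PSD, via random-phase
# spectral synthesis. Returns a zero-mean real series of length n whose
# expected variance is the PSD integral.
synth_from_psd <- function(S, fs, n) {
  stopifnot(length(S) == n %/% 2 + 1)
  df <- fs / n
  nh <- n %/% 2
  amp <- sqrt(S * df) / 2
  z <- complex(real = stats::rnorm(nh + 1), imaginary = stats::rnorm(nh + 1))
  Z <- complex(length.out = n)
  Z[1] <- 0
  Z[2:nh] <- amp[2:nh] * z[2:nh] * n
  Z[nh + 1] <- sqrt(S[nh + 1] * df) * Re(z[nh + 1]) * n
  Z[(nh + 2):n] <- Conj(Z[nh:2])
  Re(stats::fft(Z, inverse = TRUE)) / n
}

#' Generate a synthetic RR-interval series
#'
#' Simulates one recording of a given state and age group. The
#' within-subject fluctuation is a Gaussian process with the state's
#' spectral structure, synthesized on a uniform grid; beats are then
#' read out sequentially, each interval being the target mean plus the
#' fluctuation value at the current beat time. Identical seeds and
#' arguments give bitwise-identical series.
#'
#' @param state `"BSL"`, `"Anesthesia"` or `"ABK"`.
#' @param age_group `"young"` or `"adult"`.
#' @param params optional [state_params()] override.
#' @param duration recording length in seconds (> 0).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param config configuration list.
#' @return An [rr_series] with metadata filled in.
#' @export
generate_rr_series <- function(state, age_group, params = NULL,
                               duration = 600, seed = NULL,
                               config = sanclock_defaults()) {
  if (!state %in% c("BSL", "Anesthesia", "ABK"))
    stop("unknown state label: ", state)
  if (!age_group %in% c("young", "adult"))
    stop("unknown age group label: ", age_group)
  if (duration <= 0) stop("duration must be positive")
  if (is.null(params)) params <- state_params(age_group, state, config)
  validate_state_params(params)
  if (!is.null(seed)) set.seed(seed)

  fs <- config$grid_fs
  n <- 2^ceiling(log2((duration + 60) * fs))
  freqs <- seq(0, n %/% 2) * fs / n
  S <- state_psd(params, freqs, config)
  x <- if (all(S == 0)) numeric(n) else synth_from_psd(S, fs, n)

  t_grid <- seq(0, by = 1 / fs, length.out = n)
  xf <- stats::approxfun(t_grid, x, rule = 2)
  rr <- numeric(ceiling(duration / 0.28) + 1)
  t_cur <- 0
  k <- 0L
  while (t_cur <= duration) {
    iv <- params$mean_bi + xf(t_cur)
    iv <- min(max(iv, 280.5), 2399.5)   # keep inside physiological range
    k <- k + 1L
    rr[k] <- iv
    t_cur <- t_cur + iv / 1000
  }
  rr_series(rr[seq_len(k)] / 1000,
            meta = list(group = age_group, state = state,
                        age = params$age %||% NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic cohort across states
#'
#' Draws per-subject ages and per-subject-state mean beat intervals
#' (state mean plus Gaussian inter-subject spread), then simulates one
#' recording per subject and state.
#'
#' @param n_young,n_adult cohort sizes (defaults 16 and 23).
#' @param states subset of the three states to simulate.
#' @param duration recording length in seconds.
#' @param seed integer seed for the whole cohort.
#' @param config configuration list.
#' @return A list of records, each
#'   `list(subject_id, age, group, state, series)`, with class
#'   `rr_cohort`.
#' @export
generate_cohort <- function(n_young = NULL, n_adult = NULL,
                            states = c("BSL", "Anesthesia", "ABK"),
                            duration = NULL, seed = 1,
                            config = sanclock_defaults()) {
  n_young <- n_young %||% config$cohort$n_young
  n_adult <- n_adult %||% config$cohort$n_adult
  duration <- duration %||% config$cohort$duration
  if (n_young + n_adult == 0) stop("empty cohort")
  set.seed(seed)
  recs <- list()
  sid <- 0L
  for (group in c("young", "adult")) {
    ng <- if (group == "young") n_young else n_adult
    if (ng == 0) next
    ar <- config$cohort[[paste0("ages_", group)]]
    ages <- stats::runif(ng, ar[1], ar[2])
    for (i in seq_len(ng)) {
      sid <- sid + 1L
      for (state in states) {
        p <- state_params(group, state, config)
        p$mean_bi <- p$mean_bi + stats::rnorm(1, 0, p$subject_sd)
        p$mean_bi <- min(max(p$mean_bi, 300), 2300)
        p$age <- ages[i]
        sseed <- sample.int(.Machine$integer.max - 1L, 1)
        s <- generate_rr_series(state, group, params = p,
                                duration = duration, seed = sseed,
                                config = config)
        s$meta$subject_id <- sprintf("S%03d", sid)
        recs[[length(recs) + 1L]] <-
          list(subject_id = s$meta$subject_id, age = ages[i],
               group = group, state = state, series = s)
      }
    }
  }
  structure(recs, class = "rr_cohort")
}

#' @export
print.rr_cohort <- function(x, ...) {
  ids <- unique(vapply(x, `[[`, character(1), "subject_id"))
  st <- table(vapply(x, `[[`, character(1), "state"))
  cat("Synthetic RR cohort:", length(ids), "subjects,",
      length(x), "recordings\n")
  print(st)
  invisible(x)
}

#' Generate an autonomic-blockade cohort following the age law
#'
#' Each subject's target mean beat interval is
#' `intercept + slope * age + N(0, noise_sd)`; series are generated with
#' the ABK spectral structure of the subject's age group. The default
#' age span is the union of both groups' ranges (5-78 years) so the
#' slope is identifiable.
#'
#' @param n number of subjects (used when `ages` is `NULL`).
#' @param ages optional vector of ages in years.
#' @param law list with `intercept` (ms), `slope` (ms/year) and
#'   `noise_sd` (ms); defaults to the packaged law.
#' @param duration recording length in seconds.
#' @param seed integer seed.
#' @param config configuration list.
#' @return A list of `list(age, series)` records with class
#'   `abk_cohort`.
#' @export
generate_abk_cohort <- function(n = 60, ages = NULL, law = NULL,
                                duration = NULL, seed = 1,
                                config = sanclock_defaults()) {
  law <- law %||% config$age_law
  duration <- duration %||% config$cohort$duration
  set.seed(seed)
  if (is.null(ages)) ages <- stats::runif(n, 5, 78)
  if (length(ages) == 0) stop("empty age list")
  recs <- vector("list", length(ages))
  for (i in seq_along(ages)) {
    group <- if (ages[i] < 21) "young" else "adult"
    p <- state_params(group, "ABK", config)
    p$mean_bi <- law$intercept + law$slope * ages[i] +
      stats::rnorm(1, 0, law$noise_sd)
    p$mean_bi <- min(max(p$mean_bi, 300), 2300)
    p$age <- ages[i]
    sseed <- sample.int(.Machine$integer.max - 1L, 1)
    recs[[i]] <- list(age = ages[i],
                      series = generate_rr_series("ABK", group, params = p,
                                                  duration = duration,
                                                  seed = sseed,
                                                  config = config))
  }
  structure(recs, class = "abk_cohort")
}

#' Inject ectopic beats and out-of-range outliers
#'
#' Ectopic beats are modeled as a short interval followed by a
#' compensatory long one (their sum is preserved); outliers replace
#' single intervals with values outside the physiological 0.28-2.4 s
#' range. Ground-truth positions are recorded so cleaning filters can be
#' validated against them.
#'
#' @param series an [rr_series].
#' @param n_ectopic number of ectopic pairs to inject.
#' @param n_outlier number of out-of-range outliers to inject.
#' @param seed integer seed.
#' @return The corrupted [rr_series]; attribute `artifact_idx` holds
#'   `list(ectopic = <beat indices, both of each pair>, outlier = ...)`.
#' @export
inject_artifacts <- function(series, n_ectopic = 0, n_outlier = 0,
                             seed = NULL) {
  stopifnot(inherits(series, "rr_series"))
  n <- length(series$intervals)
  if (2 * n_ectopic + n_outlier > 0.2 * n)
    stop("artifact counts exceed 20% of beats")
  if (n_ectopic == 0 && n_outlier == 0) return(series)
  if (!is.null(seed)) set.seed(seed)
  rr <- series$intervals
  # pick well-separated interior positions so artifacts do not interact
  need <- n_ectopic + n_outlier
  cand <- seq(15L, n - 15L)
  pos <- integer(0)
  for (p in sample(cand)) {
    if (all(abs(p - pos) > 25L)) pos <- c(pos, p)
    if (length(pos) == need) break
  }
  if (length(pos) < need)
    stop("series too short to place the requested artifacts")
  ect <- sort(pos[seq_len(n_ectopic)])
  out <- sort(pos[n_ectopic + seq_len(n_outlier)])
  for (i in ect) {
    tot <- rr[i] + rr[i + 1]
    rr[i] <- 0.5 * rr[i]
    rr[i + 1] <- tot - rr[i]
  }
  if (n_outlier > 0) {
    long <- stats::runif(n_outlier) < 0.5
    rr[out] <- ifelse(long, stats::runif(n_outlier, 2.5, 3.2),
                      stats::runif(n_outlier, 0.08, 0.2))
  }
  res <- rr_series(rr, meta = series$meta)
  attr(res, "artifact_idx") <- list(ectopic = sort(c(ect, ect + 1L)),
                                    outlier = out)
  res
}
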