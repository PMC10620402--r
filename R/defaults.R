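.sanclock_env <- new.env(parent = emptyenv())

#' Packaged default configuration
#'
#' Returns the default configuration shipped with the package: per-state
#' generator parameters (mean beat interval, inter-subject spread,
#' spectral amplitudes), the age-linear autonomic-blockade law, HRV band
#' schemes, multiscale-entropy parameters, cleaning thresholds, cohort
#' sizes and the four signature-filter presets. Pass `path` to load a
#' user configuration with the same YAML layout.
#'
#' @param path optional path to a YAML configuration file.
#' @return A nested named list.
#' @export
sanclock_defaults <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.sanclock_env$defaults)) {
      p <- system.file("extdata", "defaults.yaml", package = "sanclock")
      .sanclock_env$defaults <- yaml::read_yaml(p)
    }
    return(.sanclock_env$defaults)
  }
  yaml::read_yaml(path)
}

#' Generator parameters for one state and age group
#'
#' @param group `"young"` or `"adult"`.
#' @param state `"BSL"`, `"Anesthesia"` or `"ABK"`.
#' @param config configuration list, see [sanclock_defaults()].
#' @return A `state_params` list with fields `mean_bi` (ms),
#'   `subject_sd` (ms), `band_amp` (ms RMS per VLF/LF/HF band),
#'   `one_over_f_amp` (ms), `resp_peak`, `total_sd` (ms) and `shape`
#'   (signature presets applied to the basal spectrum).
#' @export
state_params <- function(group = c("young", "adult"),
                         state = c("BSL", "Anesthesia", "ABK"),
                         config = sanclock_defaults()) {
  group <- match.arg(group)
  state <- match.arg(state)
  p <- config$states[[group]][[state]]
  if (is.null(p)) stop("no parameters for ", group, "/", state)
  p$group <- group
  p$state <- state
  validate_state_params(p)
  structure(p, class = "state_params")
}

validate_state_params <- function(p) {
  amps <- c(unlist(p$band_amp), p$one_over_f_amp,
            if (!is.null(p$resp_peak)) p$resp_peak$amp, p$subject_sd)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  if (p$mean_bi < 280 || p$mean_bi > 2400)
    stop("mean_bi must lie in [280, 2400] ms")
  invisible(p)
}

#' Standard HRV band scheme
#'
#' @param scheme `"standard"` (HF 0.15-0.4 Hz) or `"wide_hf"` (HF
#'   0.15-0.6 Hz, matching the upper edge of the ABK signature filters).
#' @param config configuration list.
#' @return A `band_scheme` list with `vlf`, `lf`, `hf` edges in Hz.
#' @export
band_scheme <- function(scheme = c("standard", "wide_hf"),
                        config = sanclock_defaults()) {
  scheme <- match.arg(scheme)
  b <- if (scheme == "standard") config$bands else config$bands_wide_hf
  edges <- unlist(b)
  if (any(diff(edges) < 0)) stop("band edges must be increasing")
  structure(b, class = "band_scheme")
}
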