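#' Run the full synthetic study end to end
#'
#' Orchestrates the whole pipeline: cohort simulation, cleaning,
#' time-domain / band-power / multiscale-entropy tables, signature
#' filtering of the appropriate source state for each preset,
#' MSE-similarity reports against the matching target state, the
#' autonomic-blockade age regression, and a JSON manifest tying the
#' outputs to the configuration hash and seed. Every step is also
#' usable standalone on user-supplied RR files via the exported module
#' functions.
#'
#' @param output_dir writable output directory (created if missing).
#' @param config configuration list, see [sanclock_defaults()].
#' @param seed integer seed governing all randomness.
#' @param n_young,n_adult,duration optional overrides of the configured
#'   cohort.
#' @param n_abk size of the autonomic-blockade age-regression cohort.
#' @param mse_scales maximum MSE scale used in the similarity reports.
#' @return The manifest, invisibly: a list with the seed, config hash,
#'   subject count and the paths of every file written.
#' @export
run_full_study <- function(output_dir, config = sanclock_defaults(),
                           seed = 1, n_young = NULL, n_adult = NULL,
                           duration = NULL, n_abk = 60, mse_scales = NULL) {
  n_young <- n_young %||% config$cohort$n_young
  n_adult <- n_adult %||% config$cohort$n_adult
  duration <- duration %||% config$cohort$duration
  S <- mse_scales %||% config$mse$S
  if (n_young + n_adult == 0) stop("empty cohort in configuration")
  if (duration < 180) stop("recordings shorter than 180 s are not usable")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(name) {
    p <- file.path(output_dir, name)
    paths[[length(paths) + 1]] <<- p
    p
  }

  cohort <- generate_cohort(n_young = n_young, n_adult = n_adult,
                            duration = duration, seed = seed,
                            config = config)
  dir.create(file.path(output_dir, "series"), showWarnings = FALSE)
  for (rec in cohort) {
    nm <- sprintf("%s_%s_%s.csv", rec$subject_id, rec$group, rec$state)
    write_rr(rec$series, put(file.path("series", nm)))
  }

  cleaned <- lapply(cohort, function(rec) {
    rec$series <- preprocess_pipeline(rec$series, config)$series
    rec
  })
  metrics <- biv_table(cleaned, clean = FALSE, config = config)
  utils::write.csv(metrics, put("metrics.csv"), row.names = FALSE)

  bp <- do.call(rbind, lapply(cleaned, function(rec) {
    sp <- band_powers(compute_psd(rec$series), "standard", config)
    data.frame(subject_id = rec$subject_id, group = rec$group,
               state = rec$state,
               t(sp$band_power_abs), total = sp$total_power,
               t(stats::setNames(sp$band_power_norm,
                                 paste0(names(sp$band_power_norm), "_norm"))))
  }))
  utils::write.csv(bp, put("band_powers.csv"), row.names = FALSE)

  curves <- lapply(cleaned, function(rec)
    multiscale_entropy(rec$series, S = S, m = config$mse$m,
                       r_fraction = config$mse$r_fraction))
  mse_tab <- do.call(rbind, Map(function(rec, cv)
    data.frame(subject_id = rec$subject_id, group = rec$group,
               state = rec$state, scale = cv$scale, sampen = cv$sampen),
    cleaned, curves))
  utils::write.csv(mse_tab, put("mse.csv"), row.names = FALSE)

  # signature-filter emulation + similarity vs the matched target state
  presets <- signature_presets(config)
  sims <- list()
  for (nm in names(presets)) {
    grp <- sub("-.*$", "", nm)
    src_state <- attr(presets[[nm]], "source_state")
    tgt_state <- attr(presets[[nm]], "target_state")
    pick <- function(st) which(vapply(cleaned, function(r)
      r$group == grp && r$state == st, logical(1)))
    si <- pick(src_state)
    ti <- pick(tgt_state)
    if (length(si) < 2 || length(ti) < 2) next
    fc <- lapply(si, function(i) {
      f <- apply_signature(cleaned[[i]]$series, presets[[nm]],
                           fs = config$grid_fs, config = config)
      multiscale_entropy(f, S = S, m = config$mse$m,
                         r_fraction = config$mse$r_fraction)
    })
    sim <- mse_similarity(fc, curves[ti], paired = FALSE)
    sims[[nm]] <- list(preset = nm, source_state = src_state,
                       target_state = tgt_state,
                       mean_p = sim$mean_p,
                       per_scale_p = sim$per_scale_p)
  }
  jsonlite::write_json(sims, put("similarity.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  abk <- generate_abk_cohort(n = n_abk, seed = seed + 1000L,
                             duration = duration, config = config)
  avnn <- vapply(abk, function(r)
    time_domain_metrics(preprocess_pipeline(r$series, config)$series)$avnn,
    numeric(1))
  ages <- vapply(abk, `[[`, numeric(1), "age")
  fit_rr <- fit_age_law(ages, avnn, "rr")
  fit_hr <- fit_age_law(ages, avnn, "hr")
  reg <- data.frame(space = c("rr", "hr"),
                    intercept = c(fit_rr$intercept, fit_hr$intercept),
                    slope = c(fit_rr$slope, fit_hr$slope),
                    se_intercept = c(fit_rr$se_intercept, fit_hr$se_intercept),
                    se_slope = c(fit_rr$se_slope, fit_hr$se_slope),
                    r_squared = c(fit_rr$r_squared, fit_hr$r_squared),
                    n = c(fit_rr$n, fit_hr$n))
  utils::write.csv(reg, put("age_regression.csv"), row.names = FALSE)

  manifest <- list(seed = seed,
                   config_hash = config_hash(config),
                   n_subjects = n_young + n_adult,
                   n_young = n_young, n_adult = n_adult,
                   duration_s = duration,
                   n_recordings = length(cohort),
                   files = unlist(paths))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
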