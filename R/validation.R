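#' MSE-based similarity between two groups of recordings
#'
#' Scores how statistically indistinguishable two groups of multiscale
#' entropy curves are: a two-sided t-test is run at every common scale
#' (paired when the groups are the same subjects, Welch otherwise) and
#' the p-values are averaged across scales. A high mean p-value means
#' the filtered and target-state recordings share their complexity
#' profile; a low one means they differ.
#'
#' Curves with more than 25% undefined scales are excluded with a
#' warning. Degenerate zero-variance comparisons with equal means (a
#' group against itself) score p = 1 by convention.
#'
#' @param group_a,group_b lists of `mse_curve` objects.
#' @param paired `TRUE` when the two groups are the same subjects in
#'   the same order.
#' @return A `similarity_result` with `per_scale_p`, `mean_p`,
#'   `test_used` and `n_pairs`.
#' @export
mse_similarity <- function(group_a, group_b, paired = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("at least 2 curves per group are required")
  drop_bad <- function(g, label) {
    ok <- vapply(g, function(cv) mean(is.na(cv$sampen)) <= 0.25,
                 logical(1))
    if (any(!ok))
      warning(sum(!ok), " curve(s) in ", label,
              " excluded (> 25% undefined scales)")
    g[ok]
  }
  group_a <- drop_bad(group_a, "group A")
  group_b <- drop_bad(group_b, "group B")
  scales <- Reduce(intersect, lapply(c(group_a, group_b),
                                     function(cv) cv$scale))
  if (length(scales) == 0) stop("no common scales between the groups")
  mat <- function(g) vapply(g, function(cv)
    cv$sampen[match(scales, cv$scale)], numeric(length(scales)))
  A <- mat(group_a)
  B <- mat(group_b)
  pv <- vapply(seq_along(scales), function(i) {
    a <- A[i, ]
    b <- B[i, ]
    if (paired) {
      keep <- !is.na(a) & !is.na(b)
      d <- a[keep] - b[keep]
      if (length(d) < 2) return(NA_real_)
      if (all(abs(d) < 1e-12)) return(1)
      return(stats::t.test(d)$p.value)
    }
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12)
      return(if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  structure(list(scales = scales, per_scale_p = pv,
                 mean_p = mean(pv, na.rm = TRUE),
                 test_used = if (paired) "paired t" else "Welch t",
                 n_pairs = c(length(group_a), length(group_b))),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "MSE similarity (%s test, %d vs %d curves): mean p = %.3f over %d scales\n",
    x$test_used, x$n_pairs[1], x$n_pairs[2], x$mean_p,
    sum(!is.na(x$per_scale_p))))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values for the post-hoc pairwise comparisons;
#' monotone after sorting and capped at 1.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Linear age regression of beat interval or heart rate
#'
#' Ordinary least squares of a per-subject summary against age, as used
#' for the autonomic-blockade age law (`RR = intercept + slope * age`,
#' in ms) and its heart-rate-space counterpart (the intrinsic-heart-rate
#' law, in bpm, with `HR = 60000 / mean RR`).
#'
#' @param ages numeric vector of ages in years (>= 3 distinct values).
#' @param values per-subject mean beat interval (ms) when
#'   `space = "rr"`, or per-subject mean RR (ms) to be converted when
#'   `space = "hr"`.
#' @param space `"rr"` fits the values as is; `"hr"` converts mean RR to
#'   heart rate (bpm) before fitting.
#' @return An `age_law_fit` with `intercept`, `slope`, `se_intercept`,
#'   `se_slope`, `ci_intercept`, `ci_slope` (95%), `r_squared`, `n` and
#'   the underlying `lm` fit.
#' @export
fit_age_law <- function(ages, values, space = c("rr", "hr")) {
  space <- match.arg(space)
  if (length(unique(ages)) < 3)
    stop("at least 3 distinct ages are required")
  y <- if (space == "hr") 60000 / values else values
  fit <- stats::lm(y ~ ages)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 se_intercept = sm$coefficients[1, 2],
                 se_slope = sm$coefficients[2, 2],
                 ci_intercept = ci[1, ], ci_slope = ci[2, ],
                 r_squared = sm$r.squared, n = length(ages),
                 space = space, model = fit),
            class = "age_law_fit")
}

#' @export
print.age_law_fit <- function(x, ...) {
  unit <- if (x$space == "hr") "bpm" else "ms"
  cat(sprintf("Age law (%s space, n = %d): %s = %.2f %+.3f * age\n",
              x$space, x$n, if (x$space == "hr") "HR" else "RR",
              x$intercept, x$slope))
  cat(sprintf("  intercept SE %.2f %s, slope SE %.3f %s/yr, r^2 = %.3f\n",
              x$se_intercept, unit, x$se_slope, unit, x$r_squared))
  invisible(x)
}

#' @export
coef.age_law_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Held-out emulation-fidelity experiment for a signature preset
#'
#' The validation protocol for one signature filter: simulate independent
#' held-out cohorts of the preset's source and target states, filter the
#' source recordings, and score the MSE similarity of (a) filtered vs
#' target ("emulation") and (b) unfiltered source vs target ("control").
#' A faithful filter gives a high emulation mean p (the filtered series
#' are statistically indistinguishable from the target state) together
#' with a low control mean p (the states themselves differ). The
#' experiment is replicated on independent cohorts and the median of
#' each mean p is reported, stabilizing the stochastic criterion.
#'
#' @param preset preset name (see [signature_presets()]).
#' @param seed integer seed.
#' @param n subjects per arm (default from the configuration).
#' @param duration recording length in seconds (default configuration:
#'   900 s, the 10-15 min segments recorded for the drug states).
#' @param replicates number of independent cohort replicates.
#' @param config configuration list.
#' @return List with `emulation_p` and `control_p` (medians across
#'   replicates), the per-replicate values, and the experiment settings.
#' @export
emulation_fidelity <- function(preset, seed = 1, n = NULL, duration = NULL,
                               replicates = NULL,
                               config = sanclock_defaults()) {
  n <- n %||% config$emulation$n_per_group
  duration <- duration %||% config$emulation$duration
  replicates <- replicates %||% config$emulation$replicates
  pre <- signature_presets(config)[[preset]]
  if (is.null(pre)) stop("unknown preset: ", preset)
  grp <- sub("-.*$", "", preset)
  src <- attr(pre, "source_state")
  tgt <- attr(pre, "target_state")
  mse_par <- config$mse
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, 2L * replicates)
  make_arm <- function(state, sd0) {
    set.seed(sd0)
    seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
    lapply(seq_len(n), function(i) {
      p <- state_params(grp, state, config)
      set.seed(seeds[i])
      p$mean_bi <- min(max(p$mean_bi + stats::rnorm(1, 0, p$subject_sd),
                           300), 2300)
      s <- generate_rr_series(state, grp, params = p, duration = duration,
                              seed = seeds[n + i], config = config)
      preprocess_pipeline(s, config)$series
    })
  }
  one_rep <- function(k) {
    src_series <- make_arm(src, rep_seeds[2 * k - 1])
    tgt_series <- make_arm(tgt, rep_seeds[2 * k])
    curves <- function(xs) lapply(xs, multiscale_entropy, S = mse_par$S,
                                  m = mse_par$m,
                                  r_fraction = mse_par$r_fraction)
    filt <- lapply(src_series, apply_signature, spec = pre,
                   fs = config$grid_fs, config = config)
    c(emulation = mse_similarity(curves(filt), curves(tgt_series))$mean_p,
      control = mse_similarity(curves(src_series),
                               curves(tgt_series))$mean_p)
  }
  res <- vapply(seq_len(replicates), one_rep, numeric(2))
  list(preset = preset, emulation_p = stats::median(res["emulation", ]),
       control_p = stats::median(res["control", ]),
       per_replicate = res, n = n, duration = duration,
       replicates = replicates)
}
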