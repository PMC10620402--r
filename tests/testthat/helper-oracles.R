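# Brute-force oracles, kept deliberately independent of the package's
# implementation paths.

# Richman-Moorman sample entropy by explicit template enumeration.
oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0
  B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Benjamini-Hochberg step-up from its definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run_min <- Inf
  for (k in m:1) {
    run_min <- min(run_min, m * p[o[k]] / k)
    adj[o[k]] <- min(run_min, 1)
  }
  adj
}

# Per-beat brute-force versions of the three cleaning rules.
oracle_range_keep <- function(rr, lo = 0.28, hi = 2.4) rr >= lo & rr <= hi

oracle_mavg_keep <- function(rr, window = 21, threshold = 0.2) {
  n <- length(rr)
  h <- (window - 1) / 2
  keep <- logical(n)
  for (i in seq_len(n)) {
    idx <- setdiff(max(1, i - h):min(n, i + h), i)
    lm <- mean(rr[idx])
    keep[i] <- abs(rr[i] - lm) / lm <= threshold
  }
  keep
}

oracle_quotient_keep <- function(rr, threshold = 0.2) {
  n <- length(rr)
  keep <- logical(n)
  for (i in seq_len(n)) {
    bad <- FALSE
    if (i > 1) {
      q <- rr[i] / rr[i - 1]
      if (q < 1 - threshold || q > 1 + threshold) bad <- TRUE
    }
    if (i < n) {
      q <- rr[i] / rr[i + 1]
      if (q < 1 - threshold || q > 1 + threshold) bad <- TRUE
    }
    keep[i] <- !bad
  }
  keep
}

# A quiet low-variability series useful as an artifact background.
quiet_series <- function(n = 600, mean_s = 0.8, sd_s = 0.002, seed = 1) {
  set.seed(seed)
  rr_series(pmax(stats::rnorm(n, mean_s, sd_s), 0.3))
}
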