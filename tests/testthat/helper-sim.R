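# Test scaffolding: direct simulation of (possibly time-varying) AR(1) paths
# on an unbounded continuous scale, so parameter-recovery checks are not
# confounded by the device's clipping/rounding, plus a lag-pair constructor.

sim_ar_path <- function(n, b0, b1, noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b0 <- rep_len(b0, n)
  b1 <- rep_len(b1, n)
  y <- numeric(n)
  prev <- b0[1] / (1 - b1[1])
  eps <- rnorm(n, 0, noise_sd)
  for (t in seq_len(n)) {
    y[t] <- b0[t] + b1[t] * prev + eps[t]
    prev <- y[t]
  }
  y
}

# lag pairs straight from a numeric path (response epoch t is 0-based, as in
# build_lag_pairs)
make_pairs <- function(y) {
  pairs <- data.frame(t = seq_along(y)[-1] - 1L,
                      y_prev = y[-length(y)], y = y[-1])
  class(pairs) <- c("lag_pairs", "data.frame")
  pairs
}

# OLS AR(1) oracle: intercept and slope
ols_ar1 <- function(pairs) unname(coef(lm(y ~ y_prev, data = pairs)))

# residual-on-residual partial correlation oracle
partial_r_oracle <- function(x, y, z) {
  cor(residuals(lm(x ~ z)), residuals(lm(y ~ z)))
}

# a small regular observed-only stress series from integer values
make_series <- function(values, epoch_minutes = 3,
                        start = as.POSIXct("2020-01-06 00:00:00", tz = "UTC"),
                        code = NULL, id = "test") {
  n <- length(values)
  if (is.null(code)) code <- rep("observed", n)
  vals <- ifelse(code == "observed", values, NA_real_)
  stress_series(start + (seq_len(n) - 1) * epoch_minutes * 60, vals, code,
                epoch_minutes = epoch_minutes, patient_id = id)
}

# bundled cohort table; one printed GAD-7 sum sits a point above the nominal
# scale maximum, so ingestion warns
fixture_outcomes <- function() suppressWarnings(read_outcomes(example_outcomes_path()))

# independent exhaustive change-point oracle: one direct augmented fit per
# admissible candidate epoch (no incremental updates)
brute_force_cp <- function(pairs, window, cfg, gradual) {
  sub <- pairs[pairs$t >= window[1] & pairs$t < window[2], ]
  tt <- sort(sub$t)
  cand <- unique(tt)
  left_n <- findInterval(cand - 0.5, tt)
  ok <- left_n >= cfg$min_segment & (length(tt) - left_n) >= cfg$min_segment &
    (cand - window[1]) >= cfg$boundary_margin &
    (window[2] - cand) >= cfg$boundary_margin
  cand <- cand[ok]
  dd <- vapply(cand, function(cp) delta_aic(sub, cp, cfg, gradual = gradual),
               numeric(1))
  list(cp_epoch = cand[which.min(dd)], delta_aic = min(dd), cand = cand, dd = dd)
}
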