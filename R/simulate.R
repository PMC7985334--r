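#' Specify one regime of a piecewise time-varying AR(1)
#'
#' Within a regime, the latent stress process follows
#' `x_t = b0(t) + b1(t) * x_{t-1} + e_t` with sinusoidal drift
#' `b0(t) = intercept_base + drift_amplitude_intercept * sin(2*pi*(t - start)/drift_period)`
#' and analogously for the AR coefficient. Regime boundaries are the true
#' change points. Stationarity at every instant requires
#' `|ar_base| + |drift_amplitude_ar| < 1`.
#'
#' @param start_epoch 0-based grid index at which the regime begins; the first
#'   regime of a series must start at 0.
#' @param intercept_base intercept level (stress units).
#' @param ar_base autoregressive coefficient, in (-1, 1).
#' @param drift_amplitude_intercept amplitude of smooth intercept drift (stress units).
#' @param drift_amplitude_ar amplitude of smooth AR-coefficient drift.
#' @param drift_period drift period in epochs (default 480 = one day at 3 min).
#' @return a `regime_spec` list.
#' @export
regime_spec <- function(start_epoch, intercept_base, ar_base,
                        drift_amplitude_intercept = 0, drift_amplitude_ar = 0,
                        drift_period = 480) {
  if (abs(ar_base) + abs(drift_amplitude_ar) >= 1)
    stop("non-stationary regime: |ar_base| + |drift_amplitude_ar| must be < 1")
  if (drift_period <= 0) stop("drift_period must be positive")
  if (start_epoch < 0) stop("start_epoch must be >= 0")
  structure(list(start_epoch = as.integer(start_epoch),
                 intercept_base = intercept_base, ar_base = ar_base,
                 drift_amplitude_intercept = drift_amplitude_intercept,
                 drift_amplitude_ar = drift_amplitude_ar,
                 drift_period = drift_period),
            class = "regime_spec")
}

#' Specify the missingness mechanisms of a simulated export
#'
#' Three mechanisms mirror what wearable stress exports exhibit:
#' i.i.d. per-epoch insufficient-data codes (-1), episodic physical-activity
#' blocks (-2; block count Poisson per day, block length 1 + Geometric so the
#' mean equals `activity_block_length`), and whole rows silently absent from
#' the file.
#'
#' @param p_insufficient per-epoch probability of code -1.
#' @param activity_block_rate expected activity blocks per day.
#' @param activity_block_length mean block length in epochs (>= 1).
#' @param p_row_dropped per-epoch probability the row is absent entirely.
#' @return a `missingness_spec` list.
#' @export
missingness_spec <- function(p_insufficient = 0.05, activity_block_rate = 2,
                             activity_block_length = 10, p_row_dropped = 0.02) {
  p <- c(p_insufficient, p_row_dropped)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (activity_block_rate < 0) stop("activity_block_rate must be >= 0")
  if (activity_block_length < 1) stop("activity_block_length must be >= 1")
  structure(list(p_insufficient = p_insufficient,
                 activity_block_rate = activity_block_rate,
                 activity_block_length = activity_block_length,
                 p_row_dropped = p_row_dropped),
            class = "missingness_spec")
}

no_missingness <- function() missingness_spec(0, 0, 1, 0)

validate_regimes <- function(regimes, n) {
  if (!length(regimes)) stop("at least one regime is required")
  if (inherits(regimes, "regime_spec")) regimes <- list(regimes)
  starts <- vapply(regimes, function(r) r$start_epoch, integer(1))
  if (starts[1] != 0L) stop("first regime must start at epoch 0")
  if (is.unsorted(starts, strictly = TRUE))
    stop("regime start epochs must be strictly increasing")
  if (any(starts >= n)) stop("regime start beyond grid length")
  regimes
}

#' Simulate a wearable stress series with known ground truth
#'
#' Generates a latent piecewise time-varying AR(1) process on a regular
#' epoch grid, with smooth sinusoidal parameter drift within regimes and
#' abrupt parameter jumps at regime boundaries, then produces the observed
#' series the device would export: the latent value clipped to \[0, 100\] and
#' rounded to an integer (device granularity), with the three missingness
#' mechanisms applied afterwards. The latent state itself evolves unclipped so
#' the AR dynamics are undistorted at the scale boundaries.
#'
#' @param regimes list of [regime_spec()] (or a single one).
#' @param missing a [missingness_spec()]; default [missingness_spec()] defaults.
#' @param n_days number of days (default 14).
#' @param epoch_minutes epoch length; must divide 1440 (default 3).
#' @param noise_sd innovation SD in stress units (default 8).
#' @param seed integer seed; identical seed gives identical output.
#' @param epoch_start first timestamp (UTC).
#' @param patient_id identifier.
#' @return a list with `series` (a regular [stress_series()]) and `truth`
#'   (a `simulation_truth`: `cp_epochs`, per-epoch `intercept_curve` and
#'   `ar_curve`, `latent`, and `missing_mask`).
#' @export
simulate_stress_series <- function(regimes, missing = missingness_spec(),
                                   n_days = 14, epoch_minutes = 3,
                                   noise_sd = 8, seed = NULL,
                                   epoch_start = as.POSIXct("2020-01-06 00:00:00", tz = "UTC"),
                                   patient_id = "sim") {
  if (n_days < 1) stop("n_days must be >= 1")
  if (1440 %% epoch_minutes != 0) stop("epoch_minutes must divide 1440")
  n <- as.integer(n_days * 1440 / epoch_minutes)
  if (n == 0L) stop("grid length 0")
  regimes <- validate_regimes(regimes, n)
  if (!is.null(seed)) set.seed(seed)

  starts <- vapply(regimes, function(r) r$start_epoch, integer(1))
  bounds <- c(starts, n)
  t_all <- seq_len(n) - 1L
  b0 <- numeric(n); b1 <- numeric(n)
  for (i in seq_along(regimes)) {
    r <- regimes[[i]]
    idx <- which(t_all >= bounds[i] & t_all < bounds[i + 1])
    ph <- 2 * pi * (t_all[idx] - r$start_epoch) / r$drift_period
    b0[idx] <- r$intercept_base + r$drift_amplitude_intercept * sin(ph)
    b1[idx] <- r$ar_base + r$drift_amplitude_ar * sin(ph)
  }

  x <- numeric(n)
  eps <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  x0 <- if (abs(1 - b1[1]) > 1e-12) b0[1] / (1 - b1[1]) else b0[1]
  prev <- x0
  for (t in seq_len(n)) {
    x[t] <- b0[t] + b1[t] * prev + eps[t]
    prev <- x[t]
  }
  obs <- round(pmin(100, pmax(0, x)))

  mask <- rep("observed", n)
  if (missing$p_insufficient > 0)
    mask[runif(n) < missing$p_insufficient] <- "insufficient"
  if (missing$activity_block_rate > 0) {
    n_blocks <- rpois(1, missing$activity_block_rate * n_days)
    if (n_blocks > 0) {
      starts_b <- sample.int(n, n_blocks, replace = TRUE)
      lens <- 1 + rgeom(n_blocks, prob = 1 / missing$activity_block_length)
      for (j in seq_len(n_blocks)) {
        idx <- starts_b[j]:min(n, starts_b[j] + lens[j] - 1)
        mask[idx] <- "activity"
      }
    }
  }
  if (missing$p_row_dropped > 0)
    mask[runif(n) < missing$p_row_dropped] <- "absent"

  values <- ifelse(mask == "observed", obs, NA_real_)
  series <- stress_series(epoch_start + (t_all) * epoch_minutes * 60,
                          values, mask, epoch_minutes = epoch_minutes,
                          patient_id = patient_id)
  truth <- structure(list(cp_epochs = starts[-1], intercept_curve = b0,
                          ar_curve = b1, latent = x, missing_mask = mask),
                     class = "simulation_truth")
  list(series = series, truth = truth)
}

instrument_ranges <- function() {
  list(hscl11 = c(1, 4), oq30 = c(0, 4), gad7 = c(0, 21), phq9 = c(0, 27))
}

#' Simulate a small cohort with outcome tables linked to change-point counts
#'
#' Each synthetic patient gets a randomized number of true regime shifts
#' (abrupt intercept/AR jumps) in their two-week stress series, plus a
#' questionnaire outcome row: pre-treatment scores drawn around typical
#' outpatient levels, and session-15 scores equal to the instrument's baseline
#' mean plus `outcome_slope` per true change point (scaled per instrument to
#' its range, normalized to the 21-point GAD-7 scale) plus Gaussian noise. A negative
#' slope encodes the direction that more physiological change goes with fewer
#' self-reported symptoms. Synthetic scores are continuous within each
#' instrument's valid range.
#'
#' @param n_patients number of patients (>= 3).
#' @param outcome_slope change in GAD-7-scale score units per true change point
#'   (default -0.5).
#' @param outcome_noise_sd SD of outcome noise on the GAD-7 scale (default 1).
#' @param base_config list of arguments passed on to
#'   [simulate_stress_series()] (`n_days`, `epoch_minutes`, `noise_sd`, `missing`).
#' @param max_cps maximum number of true change points per patient (default 5).
#' @param seed integer seed.
#' @return list with `series` (list of [stress_series()]), `outcomes`
#'   (an `outcome_matrix` data frame with `n_cps_true`), and `truth`
#'   (list of `simulation_truth`).
#' @export
simulate_cohort <- function(n_patients, outcome_slope = -0.5,
                            outcome_noise_sd = 1, base_config = list(),
                            max_cps = 5, seed = NULL) {
  if (n_patients < 3) stop("n_patients must be >= 3 (correlation degenerate)")
  if (!is.null(seed)) set.seed(seed)
  cfg <- modifyList(list(n_days = 14, epoch_minutes = 3, noise_sd = 8,
                         missing = missingness_spec()), base_config)
  n <- as.integer(cfg$n_days * 1440 / cfg$epoch_minutes)

  series <- vector("list", n_patients)
  truth <- vector("list", n_patients)
  ids <- sprintf("P%02d", seq_len(n_patients))
  n_cps <- sample.int(max_cps + 1, n_patients, replace = TRUE) - 1L
  for (i in seq_len(n_patients)) {
    k <- n_cps[i]
    margin <- max(100L, n %/% 20L)
    cps <- if (k > 0) sort(sample(seq(margin, n - margin), k)) else integer(0)
    # alternate AR level across regimes so every jump is detectable in principle
    ar_levels <- rep(c(0.35, 0.7), length.out = k + 1)
    int_levels <- 40 + rep(c(-8, 8), length.out = k + 1)
    regimes <- lapply(seq_len(k + 1), function(j) {
      regime_spec(start_epoch = c(0L, cps)[j],
                  intercept_base = int_levels[j] * (1 - ar_levels[j]),
                  ar_base = ar_levels[j],
                  drift_amplitude_intercept = 2, drift_amplitude_ar = 0.05,
                  drift_period = 480)
    })
    sim <- simulate_stress_series(regimes, missing = cfg$missing,
                                  n_days = cfg$n_days,
                                  epoch_minutes = cfg$epoch_minutes,
                                  noise_sd = cfg$noise_sd,
                                  patient_id = ids[i])
    series[[i]] <- sim$series
    truth[[i]] <- sim$truth
  }

  rng <- instrument_ranges()
  base_means <- c(hscl11 = 2.3, oq30 = 2.0, gad7 = 12, phq9 = 14)
  base_sds <- c(hscl11 = 0.5, oq30 = 0.45, gad7 = 3.5, phq9 = 4.5)
  out <- data.frame(patient_id = ids, n_cps_true = n_cps,
                    mean_stress = vapply(series, function(s)
                      mean(s$values, na.rm = TRUE), numeric(1)))
  for (ins in names(rng)) {
    scale_k <- diff(rng[[ins]]) / 21   # one slope parameter, per-instrument scale
    pre <- pmin(rng[[ins]][2], pmax(rng[[ins]][1],
             rnorm(n_patients, base_means[ins], base_sds[ins])))
    # session-15 built from the instrument baseline (not the noisy pre score)
    # so the noiseless case is an exact linear map of the true CP count
    s15 <- base_means[ins] + outcome_slope * scale_k * n_cps +
      rnorm(n_patients, 0, outcome_noise_sd * scale_k)
    s15 <- pmin(rng[[ins]][2], pmax(rng[[ins]][1], s15))
    out[[paste0(ins, "_pre")]] <- pre
    out[[paste0(ins, "_s15")]] <- s15
  }
  out$n_cps <- out$n_cps_true
  class(out) <- c("outcome_matrix", "data.frame")
  list(series = series, outcomes = out, truth = truth)
}
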