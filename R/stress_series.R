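#' @importFrom stats rnorm runif rpois rgeom sd cor var coef pt predict quantile lm residuals
#' @importFrom utils read.csv write.csv head tail modifyList
#' @importFrom mgcv gam s
NULL

MISSING_CODES <- c("observed", "insufficient", "activity", "absent", "missing")

#' Construct a stress series
#'
#' A `stress_series` holds one patient's wearable EMA stress record: a vector of
#' timestamps (UTC), a stress value in \[0, 100\] per epoch where one could be
#' computed, and a per-epoch missing code. Device exports code an epoch as
#' `insufficient` (raw value -1) when too little heart-rate data was available
#' and `activity` (raw value -2) when the wearer was physically active; epochs
#' whose rows are absent from the export entirely are coded `absent` once the
#' grid has been regularized (see [regularize_grid()]).
#'
#' @param time `POSIXct` vector (UTC), strictly increasing, one per epoch.
#' @param values numeric vector; stress in \[0, 100\] where observed, `NA` otherwise.
#' @param missing_code character vector over
#'   `c("observed","insufficient","activity","absent","missing")`.
#' @param epoch_minutes epoch length in minutes (device default 3).
#' @param patient_id identifier string.
#' @return An object of class `stress_series`.
#' @export
stress_series <- function(time, values, missing_code, epoch_minutes = 3,
                          patient_id = "unknown") {
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct")
  n <- length(time)
  if (n == 0L) stop("empty series: grid length 0")
  if (length(values) != n || length(missing_code) != n)
    stop("`time`, `values` and `missing_code` must have equal length")
  if (is.unsorted(as.numeric(time), strictly = TRUE))
    stop("timestamps must be strictly increasing (duplicates or disorder)")
  if (!all(missing_code %in% MISSING_CODES))
    stop("invalid missing code(s): ",
         paste(unique(setdiff(missing_code, MISSING_CODES)), collapse = ", "))
  obs <- missing_code == "observed"
  if (any(is.na(values[obs])))
    stop("observed epochs must carry a stress value")
  if (any(!is.na(values[!obs])))
    stop("non-observed epochs must have NA values")
  if (any(values[obs] < 0 | values[obs] > 100))
    stop("observed stress values must lie in [0, 100]")
  structure(
    list(patient_id = patient_id, time = time, epoch_minutes = epoch_minutes,
         values = as.numeric(values), missing_code = missing_code),
    class = "stress_series")
}

#' @export
print.stress_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<stress_series> patient %s: %d epochs of %g min, %s .. %s\n",
              x$patient_id, n, x$epoch_minutes,
              format(x$time[1], tz = "UTC", usetz = TRUE),
              format(x$time[n], tz = "UTC", usetz = TRUE)))
  tab <- table(factor(x$missing_code, levels = MISSING_CODES))
  cat("  codes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (is_regular(x)) cat("  grid: regular\n") else cat("  grid: gapped (run regularize_grid())\n")
  invisible(x)
}

#' @export
length.stress_series <- function(x) length(x$values)

epoch_step_seconds <- function(series) series$epoch_minutes * 60

#' Is the series on a complete regular grid?
#'
#' @param series a [stress_series()].
#' @return `TRUE` when consecutive timestamps all differ by exactly one epoch.
#' @export
is_regular <- function(series) {
  if (length(series$time) < 2L) return(TRUE)
  all(diff(as.numeric(series$time)) == epoch_step_seconds(series))
}

stopifnot_regular <- function(series) {
  if (!is_regular(series))
    stop("series grid is gapped; apply regularize_grid() first")
  invisible(series)
}

#' Epoch indices of a regular series
#'
#' Grid indices are 0-based: epoch k starts at `epoch_start + k * epoch_minutes`.
#'
#' @param series a regular [stress_series()].
#' @return integer vector `0:(n-1)`.
#' @export
epoch_index <- function(series) {
  stopifnot_regular(series)
  seq_along(series$values) - 1L
}

#' Timestamp of a grid epoch
#'
#' @param series a regular [stress_series()].
#' @param epoch 0-based grid index (vectorized).
#' @return `POSIXct` (UTC).
#' @export
epoch_time <- function(series, epoch) {
  series$time[1] + epoch * epoch_step_seconds(series)
}

#' Fill grid gaps with absent-row epochs
#'
#' Wearable exports can silently drop whole epochs (rows missing from the CSV
#' with no -1/-2 code). This inserts every epoch between the first and last
#' timestamp, coding inserted slots `absent`. Existing values and codes are
#' untouched, so the operation is idempotent. Timestamps that do not fall on
#' the epoch grid anchored at the first row are rejected.
#'
#' @param series a [stress_series()] (possibly gapped), sorted, duplicate-free.
#' @return a regular [stress_series()].
#' @export
regularize_grid <- function(series) {
  step <- epoch_step_seconds(series)
  off <- as.numeric(series$time) - as.numeric(series$time[1])
  bad <- which(off %% step != 0)
  if (length(bad))
    stop(sprintf("timestamp not aligned to the %g-min epoch grid at row %d (%s)",
                 series$epoch_minutes, bad[1],
                 format(series$time[bad[1]], tz = "UTC", usetz = TRUE)))
  slot <- off %/% step
  n <- slot[length(slot)] + 1
  values <- rep(NA_real_, n)
  code <- rep("absent", n)
  values[slot + 1] <- series$values
  code[slot + 1] <- series$missing_code
  stress_series(series$time[1] + (seq_len(n) - 1) * step, values, code,
                epoch_minutes = series$epoch_minutes,
                patient_id = series$patient_id)
}

#' Wear-time report and suitability check
#'
#' An epoch counts as "worn" when the device produced any record for it —
#' an observed value or an insufficient-data/activity code. Data are suitable
#' for analysis when the tracker was worn more than 50% of the time (strict).
#'
#' @param series a regular [stress_series()].
#' @return a `wear_report` list with slot counts, `wear_fraction` and `suitable`.
#' @export
wear_report <- function(series) {
  stopifnot_regular(series)
  n <- length(series$values)
  if (n == 0L) stop("empty series")
  cnt <- function(code) sum(series$missing_code == code)
  n_obs <- cnt("observed"); n_ins <- cnt("insufficient")
  n_act <- cnt("activity"); n_abs <- n - n_obs - n_ins - n_act
  wf <- (n_obs + n_ins + n_act) / n
  structure(list(patient_id = series$patient_id, n_slots = n,
                 n_observed = n_obs, n_insufficient = n_ins,
                 n_activity = n_act, n_absent = n_abs,
                 wear_fraction = wf, suitable = wf > 0.5),
            class = "wear_report")
}

#' @export
print.wear_report <- function(x, ...) {
  cat(sprintf("<wear_report> %s: %d slots, wear %.1f%% -> %s\n", x$patient_id,
              x$n_slots, 100 * x$wear_fraction,
              if (x$suitable) "suitable" else "NOT suitable (need > 50%)"))
  invisible(x)
}

#' Device stress-level categories
#'
#' The device's interpretation bands for the \[0, 100\] stress index:
#' 0–25 rest, 26–50 low, 51–75 medium, 76–100 high stress. Band edges follow
#' the integer scale (25 is rest, 26 is low).
#'
#' @param value numeric vector of stress values in \[0, 100\].
#' @return factor with levels `rest`, `low`, `medium`, `high`.
#' @export
categorize_stress <- function(value) {
  if (any(is.na(value))) stop("cannot categorize missing stress values")
  if (any(value < 0 | value > 100)) stop("stress value outside [0, 100]")
  cut(value, breaks = c(-0.5, 25.5, 50.5, 75.5, 100.5),
      labels = c("rest", "low", "medium", "high"))
}

#' Collapse missing codes for modelling
#'
#' The model makes no distinction between the reasons an epoch is unobserved:
#' insufficient-data, activity and absent-row epochs are all collapsed to a
#' single `missing` code. No imputation is performed — autoregressive lag pairs
#' are later formed from grid-adjacent observed epochs only, because imputing
#' would fabricate the autocorrelation being estimated.
#'
#' @param series a regular [stress_series()].
#' @return a [stress_series()] whose codes are `observed`/`missing` only.
#' @export
modeling_view <- function(series) {
  stopifnot_regular(series)
  code <- ifelse(series$missing_code == "observed", "observed", "missing")
  stress_series(series$time, series$values, code,
                epoch_minutes = series$epoch_minutes,
                patient_id = series$patient_id)
}

#' Excel serial day number for timestamps
#'
#' Converts UTC timestamps to the Excel 1900 date system serial number
#' (days since 1899-12-30; offset 25569 days from the Unix epoch). Provided
#' for interoperability with spreadsheet-based workflows; no leap-second
#' handling.
#'
#' @param time `POSIXct` vector.
#' @return numeric vector of serial day numbers.
#' @export
excel_serial <- function(time) as.numeric(time) / 86400 + 25569
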