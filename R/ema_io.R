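#' Parse a wearable stress CSV export
#'
#' Reads a per-epoch stress export: one row per 3-minute epoch with a
#' timestamp and a stress value in \[0, 100\], or a device missing code
#' (-1 insufficient data, -2 physical activity). Timestamps may be ISO-8601
#' UTC strings or Unix epoch seconds; the format is auto-detected. Rows are
#' sorted by time; duplicate timestamps are rejected. The returned series is
#' on the raw, possibly gapped grid — apply [regularize_grid()] before
#' analysis so silently dropped rows become `absent` epochs.
#'
#' @param path CSV file with a header row.
#' @param epoch_minutes epoch length in minutes (default 3).
#' @param column_map named character vector mapping roles to header names,
#'   e.g. `c(timestamp = "timestamp", stress = "stress")`; accommodates vendor
#'   exports with different headers.
#' @param patient_id identifier; defaults to the file name without extension.
#' @param timezone_policy only `"utc"` is supported: timestamps are taken as UTC.
#' @return a [stress_series()] on the raw grid.
#' @export
parse_stress_csv <- function(path, epoch_minutes = 3,
                             column_map = c(timestamp = "timestamp", stress = "stress"),
                             patient_id = NULL, timezone_policy = "utc") {
  timezone_policy <- match.arg(timezone_policy, "utc")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty stress file: ", path)
  for (role in c("timestamp", "stress")) {
    if (!(column_map[[role]] %in% names(df)))
      stop(sprintf("column '%s' (role %s) not found; header is: %s",
                   column_map[[role]], role, paste(names(df), collapse = ", ")))
  }
  ts_raw <- df[[column_map[["timestamp"]]]]
  time <- parse_timestamps(ts_raw)
  stress <- df[[column_map[["stress"]]]]
  if (!is.numeric(stress)) stress <- suppressWarnings(as.numeric(stress))
  bad <- which(is.na(stress) | !(stress %in% c(-1, -2) | (stress >= 0 & stress <= 100)))
  if (length(bad))
    stop(sprintf("stress value outside [0,100] U {-1,-2} at row %d: %s",
                 bad[1], as.character(df[[column_map[["stress"]]]][bad[1]])))
  ord <- order(time)
  time <- time[ord]; stress <- stress[ord]
  if (anyDuplicated(as.numeric(time)))
    stop("duplicate timestamps in stress file")
  code <- rep("observed", length(stress))
  code[stress == -1] <- "insufficient"
  code[stress == -2] <- "activity"
  values <- ifelse(code == "observed", stress, NA_real_)
  if (is.null(patient_id))
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  stress_series(time, values, code, epoch_minutes = epoch_minutes,
                patient_id = patient_id)
}

parse_timestamps <- function(x) {
  if (is.numeric(x))
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  x <- trimws(as.character(x))
  num <- suppressWarnings(as.numeric(x))
  if (!any(is.na(num)))   # all-numeric column: Unix epoch seconds
    return(as.POSIXct(num, origin = "1970-01-01", tz = "UTC"))
  clean <- sub("Z$", "", sub("T", " ", x))
  out <- as.POSIXct(clean, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  short <- is.na(out)
  out[short] <- as.POSIXct(clean[short], tz = "UTC", format = "%Y-%m-%d %H:%M")
  if (anyNA(out))
    stop(sprintf("unparseable timestamp at row %d: '%s'", which(is.na(out))[1],
                 x[which(is.na(out))[1]]))
  out
}

#' Write a stress series as a CSV export
#'
#' Inverse of [parse_stress_csv()]: writes `timestamp,stress` rows with
#' ISO-8601 UTC timestamps, encoding insufficient-data epochs as -1 and
#' activity epochs as -2. Epochs coded `absent` are omitted entirely (they
#' have no source row), so parse -> regularize round-trips the series.
#'
#' @param series a [stress_series()] (codes must not be collapsed to `missing`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stress_csv <- function(series, path) {
  if (any(series$missing_code == "missing"))
    stop("cannot write a collapsed modeling view; use the original coded series")
  keep <- series$missing_code != "absent"
  stress <- series$values[keep]
  stress[series$missing_code[keep] == "insufficient"] <- -1
  stress[series$missing_code[keep] == "activity"] <- -2
  df <- data.frame(
    timestamp = format(series$time[keep], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    stress = stress)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname wear_report
#' @param x a `wear_report`.
#' @param path output JSON file.
#' @export
write_wear_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
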