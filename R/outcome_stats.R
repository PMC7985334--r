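INSTRUMENTS <- c("hscl11", "oq30", "gad7", "phq9")

#' Read a per-patient outcome table
#'
#' One row per patient with a change-point count and questionnaire scores at
#' pre-treatment and session 15: columns `patient_id`, `n_cps`, optionally
#' `mean_stress`, and `<instrument>_pre` / `<instrument>_s15` for
#' `hscl11` (range 1–4), `oq30` (0–4), `gad7` (0–21) and `phq9` (0–27).
#' Any score cell may be empty (missing).
#'
#' @param path CSV file.
#' @return an `outcome_matrix` data frame.
#' @export
read_outcomes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_outcome_matrix(df)
}

#' @rdname read_outcomes
#' @param df a data frame with the columns described above.
#' @export
as_outcome_matrix <- function(df) {
  if (!all(c("patient_id", "n_cps") %in% names(df)))
    stop("outcome table needs `patient_id` and `n_cps` columns")
  if (any(df$n_cps < 0, na.rm = TRUE)) stop("n_cps must be >= 0")
  rng <- instrument_ranges()
  for (ins in INSTRUMENTS) {
    for (occ in c("_pre", "_s15")) {
      col <- paste0(ins, occ)
      if (!col %in% names(df)) next
      v <- df[[col]]
      out <- !is.na(v) & (v < rng[[ins]][1] | v > rng[[ins]][2])
      # warn rather than reject: published per-patient tables occasionally
      # print sums a point above the nominal scale maximum
      if (any(out))
        warning(sprintf("%s outside nominal range [%g, %g] for patient %s",
                        col, rng[[ins]][1], rng[[ins]][2],
                        df$patient_id[which(out)[1]]))
    }
  }
  class(df) <- c("outcome_matrix", "data.frame")
  df
}

#' Complete-case subset for one instrument
#'
#' Retains patients who provided the instrument's score at both pre-treatment
#' and session 15 and have a change-point count. The same subset is used for
#' pre-treatment and session-15 correlations alike, so the two columns of a
#' correlation table describe the same patients.
#'
#' @param matrix an `outcome_matrix`.
#' @param instrument one of `"hscl11"`, `"oq30"`, `"gad7"`, `"phq9"`.
#' @return the retained `outcome_matrix` rows.
#' @export
complete_cases <- function(matrix, instrument) {
  instrument <- match.arg(instrument, INSTRUMENTS)
  pre <- matrix[[paste0(instrument, "_pre")]]
  s15 <- matrix[[paste0(instrument, "_s15")]]
  if (is.null(pre) || is.null(s15))
    stop("instrument columns missing for ", instrument)
  keep <- !is.na(pre) & !is.na(s15) & !is.na(matrix$n_cps)
  out <- matrix[keep, , drop = FALSE]
  if (nrow(out) < 3)
    stop(sprintf("correlation undefined: only %d complete case(s) for %s",
                 nrow(out), instrument))
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values; take complete cases first")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: correlation undefined")
  cor(x, y)
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of `z`
#' from both: `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`.
#' Equivalent to correlating the residuals of `x` on `z` with those of `y`
#' on `z`.
#'
#' @param x,y,z numeric vectors of equal length >= 4, pairwise nonzero variance.
#' @return partial correlation coefficient in \[-1, 1\].
#' @export
partial_r <- function(x, y, z) {
  if (length(unique(c(length(x), length(y), length(z)))) != 1)
    stop("x, y, z must have equal length")
  if (length(x) < 4) stop("need at least 4 observations")
  rxy <- pearson_r(x, y); rxz <- pearson_r(x, z); ryz <- pearson_r(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("collinear control variable")
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

r_pvalue <- function(r, n) {
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Correlations of change-point counts and stress level with outcomes
#'
#' For each instrument, on its complete-case subset: means and sample SDs
#' (n-1 denominator) at pre-treatment and session 15; Pearson correlations of
#' the change-point count with the score at both occasions; the first-order
#' partial correlation at session 15 adjusting for the same instrument's
#' pre-treatment score (controlling initial impairment); and, when a
#' `mean_stress` column is present, the analogous correlations for mean
#' stress level. Two-sided p-values (t distribution, df = n - 2) are attached
#' and entries with p < 0.05 are starred; no multiplicity correction is
#' applied.
#'
#' @param matrix an `outcome_matrix`.
#' @return a `correlation_report` data frame, one row per instrument.
#' @export
correlation_table <- function(matrix) {
  has_stress <- "mean_stress" %in% names(matrix) && !all(is.na(matrix$mean_stress))
  rows <- lapply(INSTRUMENTS, function(ins) {
    cc <- complete_cases(matrix, ins)
    pre <- cc[[paste0(ins, "_pre")]]
    s15 <- cc[[paste0(ins, "_s15")]]
    row <- data.frame(
      instrument = ins, n_used = nrow(cc),
      pre_mean = mean(pre), pre_sd = sd(pre),
      s15_mean = mean(s15), s15_sd = sd(s15),
      r_cps_pre = pearson_r(cc$n_cps, pre),
      r_cps_s15 = pearson_r(cc$n_cps, s15),
      r_partial_cps = partial_r(cc$n_cps, s15, pre))
    row$p_cps_pre <- r_pvalue(row$r_cps_pre, nrow(cc))
    row$p_cps_s15 <- r_pvalue(row$r_cps_s15, nrow(cc))
    if (has_stress) {
      ccs <- cc[!is.na(cc$mean_stress), , drop = FALSE]
      if (nrow(ccs) >= 3) {
        row$r_stress_pre <- pearson_r(ccs$mean_stress, ccs[[paste0(ins, "_pre")]])
        row$r_stress_s15 <- pearson_r(ccs$mean_stress, ccs[[paste0(ins, "_s15")]])
        row$r_partial_stress <- partial_r(ccs$mean_stress,
                                          ccs[[paste0(ins, "_s15")]],
                                          ccs[[paste0(ins, "_pre")]])
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  out$sig_cps_s15 <- out$p_cps_s15 < 0.05
  rownames(out) <- NULL
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> change-point count vs outcomes (complete cases)\n")
  df <- data.frame(
    instrument = x$instrument, n = x$n_used,
    `pre M (SD)` = sprintf("%.2f (%.2f)", x$pre_mean, x$pre_sd),
    `r pre` = sprintf("%.2f", x$r_cps_pre),
    `s15 M (SD)` = sprintf("%.2f (%.2f)", x$s15_mean, x$s15_sd),
    `r s15` = sprintf("%.2f%s", x$r_cps_s15, ifelse(x$sig_cps_s15, "*", "")),
    `r partial` = sprintf("%.2f", x$r_partial_cps),
    check.names = FALSE)
  print(df, row.names = FALSE)
  cat("* p < 0.05 (two-sided, uncorrected)\n")
  invisible(x)
}
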