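#' Exhaustive change-point search within a window
#'
#' Evaluates the AIC difference of [fit_cp_ar()] versus [fit_tv_ar()] at every
#' admissible candidate epoch in the window and returns the minimizer. A
#' candidate is admissible when both resulting parts hold at least
#' `min_segment` usable lag pairs and the candidate lies at least
#' `boundary_margin` epochs from both window edges. With
#' `candidate_stride > 1` only every stride-th admissible candidate is
#' evaluated.
#'
#' The scan exploits the structure of the problem: all candidate models share
#' the gradual model's design and smoothing parameters and differ only in two
#' step columns, so cross-products against the step columns are suffix sums
#' updated incrementally across candidates and each candidate costs a pair of
#' 2x2 Schur-complement solves. The result is identical (to numerical
#' precision) to refitting the augmented model at every candidate.
#'
#' @param pairs a [build_lag_pairs()] frame.
#' @param window `c(start, end)` epoch window (half-open); defaults to the
#'   full pair range.
#' @param config a [detector_config()].
#' @param gradual optional pre-computed gradual fit on the pairs inside
#'   `window`.
#' @return `NULL` when no candidate is admissible, else a list with
#'   `cp_epoch`, `delta_aic`, and `n_candidates`.
#' @export
search_best_cp <- function(pairs, window = NULL, config = detector_config(),
                           gradual = NULL) {
  if (is.null(window))
    window <- c(min(pairs$t), max(pairs$t) + 1L)
  sub <- pairs[pairs$t >= window[1] & pairs$t < window[2], , drop = FALSE]
  n <- nrow(sub)
  if (n < 2 * config$min_segment + 1) return(NULL)
  sub <- sub[order(sub$t), , drop = FALSE]

  # admissible candidate epochs: response epochs of the pairs, interior only
  tt <- sub$t
  cand <- unique(tt)
  left_n <- findInterval(cand - 0.5, tt)      # pairs with t < cand
  ok <- left_n >= config$min_segment & (n - left_n) >= config$min_segment &
    (cand - window[1]) >= config$boundary_margin &
    (window[2] - cand) >= config$boundary_margin
  cand <- cand[ok]
  if (!length(cand)) return(NULL)
  if (config$candidate_stride > 1)
    cand <- cand[seq(1, length(cand), by = config$candidate_stride)]

  if (is.null(gradual)) gradual <- fit_tv_ar(sub, config)
  if (gradual$rank_deficient) return(NULL)
  d <- lp_design(gradual)
  X <- d$X; S <- d$S; y <- sub$y; yp <- sub$y_prev
  p <- ncol(X)

  A <- crossprod(X) + S
  Minv <- chol2inv(chol(A))
  XtX <- A - S
  c1 <- crossprod(X, y)
  Minv_c1 <- Minv %*% c1
  tr0 <- sum(Minv * S)                        # tr(M^-1 S), S symmetric
  P <- Minv %*% S %*% Minv
  yy <- sum(y^2)

  # suffix sums over pairs ordered by t
  rev_cumsum <- function(v) rev(cumsum(rev(v)))
  Sx <- apply(X, 2, function(col) rev_cumsum(col))          # n x p
  Sxz <- apply(X * yp, 2, function(col) rev_cumsum(col))
  s_n <- rev_cumsum(rep(1, n))
  s_z <- rev_cumsum(yp); s_zz <- rev_cumsum(yp^2)
  s_y <- rev_cumsum(y); s_zy <- rev_cumsum(yp * y)

  aic0 <- gradual$aic
  best_delta <- Inf; best_cp <- NA_integer_; n_eval <- 0L
  first_idx <- findInterval(cand - 0.5, tt) + 1L  # first pair with t >= cand
  for (j in seq_along(cand)) {
    k <- first_idx[j]
    G <- cbind(Sx[k, ], Sxz[k, ])                            # X'U, p x 2
    W <- matrix(c(s_n[k], s_z[k], s_z[k], s_zz[k]), 2, 2)    # U'U
    c2 <- c(s_y[k], s_zy[k])                                 # U'y
    MG <- Minv %*% G
    K <- W - crossprod(G, MG)
    Kc <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(Kc)) next                                    # collinear step
    v <- backsolve(Kc, forwardsolve(t(Kc), c2 - crossprod(G, Minv_c1)))
    b <- Minv_c1 - MG %*% v
    quad <- as.numeric(crossprod(b, XtX %*% b) + 2 * crossprod(b, G %*% v) +
                         crossprod(v, W %*% v))
    rss <- yy - 2 * (sum(b * c1) + sum(v * c2)) + quad
    rss <- max(rss, 1e-300)
    PG <- P %*% G
    edf <- (p + 2) - tr0 - sum(diag(solve(K, crossprod(G, PG))))
    aic_c <- -2 * gaussian_loglik(rss, n) + 2 * edf
    n_eval <- n_eval + 1L
    if (aic_c - aic0 < best_delta) {
      best_delta <- aic_c - aic0
      best_cp <- cand[j]
    }
  }
  if (!is.finite(best_delta)) return(NULL)
  list(cp_epoch = best_cp, delta_aic = best_delta, n_candidates = n_eval)
}

#' Prune change points that are too close together or to the boundaries
#'
#' Regimes squeezed between nearby change points hold too few measurements
#' for robust estimates, and change points near the series boundaries cannot
#' be estimated reliably, so candidates are pruned greedily: processing in
#' order of ascending AIC difference (strongest evidence first), a change
#' point is accepted iff it lies at least `min_gap` epochs from every
#' already-accepted one and at least `boundary_margin` epochs from both ends
#' of the analyzed window; the rest are excluded with reason `too_close` or
#' `boundary`.
#'
#' @param cps data frame with columns `epoch` and `delta_aic`.
#' @param config a [detector_config()].
#' @param series_range `c(start, end)` epoch range of the analyzed window.
#' @return list with `accepted` and `excluded` data frames (the latter with a
#'   `reason` column), both sorted by epoch.
#' @export
prune_change_points <- function(cps, config = detector_config(),
                                series_range = NULL) {
  empty <- data.frame(epoch = integer(0), delta_aic = numeric(0))
  if (is.null(cps) || nrow(cps) == 0L)
    return(list(accepted = empty,
                excluded = cbind(empty, reason = character(0))))
  if (is.null(series_range))
    series_range <- c(min(cps$epoch) - config$boundary_margin,
                      max(cps$epoch) + config$boundary_margin)
  ord <- order(cps$delta_aic)                  # most negative first
  acc <- integer(0)
  reason <- rep(NA_character_, nrow(cps))
  for (i in ord) {
    e <- cps$epoch[i]
    if (e - series_range[1] < config$boundary_margin ||
        series_range[2] - e < config$boundary_margin) {
      reason[i] <- "boundary"
    } else if (length(acc) && any(abs(acc - e) < config$min_gap)) {
      reason[i] <- "too_close"
    } else {
      acc <- c(acc, e)
    }
  }
  keep <- is.na(reason)
  accepted <- cps[keep, , drop = FALSE]
  accepted <- accepted[order(accepted$epoch), , drop = FALSE]
  excluded <- cps[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  excluded <- excluded[order(excluded$epoch), , drop = FALSE]
  rownames(accepted) <- rownames(excluded) <- NULL
  list(accepted = accepted, excluded = excluded)
}

#' Detect change points by recursive AIC-based segmentation
#'
#' Runs the exploratory search on the full analysis window; when the best
#' candidate's AIC difference falls below the threshold it is accepted, the
#' series is split at the change point, and both newly formed sections are
#' examined in the same way, recursively, until no section yields a
#' sub-threshold candidate (or `max_depth` is reached). The collected change
#' points are then pruned ([prune_change_points()]) and the surviving set
#' partitions the window into regimes.
#'
#' @param series a regular [stress_series()]; must be suitable
#'   (wear fraction > 0.5, see [wear_report()]).
#' @param config a [detector_config()].
#' @return a `changepoint_set`: data frames `cps` (accepted: `epoch`,
#'   `timestamp`, `delta_aic`), `excluded` (with `reason`), `regimes`
#'   (`start`/`end` half-open epoch intervals), plus the analyzed range and
#'   the configuration used. Deterministic: identical series and config give
#'   identical output.
#' @export
detect_change_points <- function(series, config = detector_config()) {
  wr <- wear_report(series)
  if (!wr$suitable)
    stop(sprintf("series unsuitable for analysis: wear_fraction %.2f <= 0.5",
                 wr$wear_fraction))
  mv <- modeling_view(series)
  pairs <- build_lag_pairs(mv, min_pairs = 2 * config$min_segment + 1)
  obs <- series$values[series$missing_code == "observed"]
  range0 <- c(min(pairs$t), max(pairs$t) + 1L)

  found <- list()
  degenerate <- FALSE
  if (sd(obs) < 1e-8) {
    warning("degenerate series: zero variance, no change points sought")
    degenerate <- TRUE
  } else {
    recurse <- function(win, depth) {
      res <- search_best_cp(pairs, window = win, config = config)
      if (is.null(res) || res$delta_aic >= config$threshold) return(invisible())
      found[[length(found) + 1L]] <<- data.frame(epoch = res$cp_epoch,
                                                 delta_aic = res$delta_aic)
      if (depth < config$max_depth) {
        recurse(c(win[1], res$cp_epoch), depth + 1L)
        recurse(c(res$cp_epoch, win[2]), depth + 1L)
      }
      invisible()
    }
    recurse(range0, 1L)
  }
  cand <- if (length(found)) do.call(rbind, found) else
    data.frame(epoch = integer(0), delta_aic = numeric(0))
  pr <- prune_change_points(cand, config, series_range = range0)

  bnd <- c(range0[1], pr$accepted$epoch, range0[2])
  regimes <- data.frame(start = bnd[-length(bnd)], end = bnd[-1])
  ts_of <- function(e) epoch_time(series, e)
  cps <- pr$accepted
  cps$timestamp <- if (nrow(cps)) ts_of(cps$epoch) else
    as.POSIXct(character(0), tz = "UTC")
  excl <- pr$excluded
  excl$timestamp <- if (nrow(excl)) ts_of(excl$epoch) else
    as.POSIXct(character(0), tz = "UTC")
  structure(list(patient_id = series$patient_id,
                 cps = cps[, c("epoch", "timestamp", "delta_aic")],
                 excluded = excl[, c("epoch", "timestamp", "delta_aic", "reason")],
                 regimes = regimes, range = range0, degenerate = degenerate,
                 config = config),
            class = "changepoint_set")
}

#' @export
print.changepoint_set <- function(x, ...) {
  cat(sprintf("<changepoint_set> patient %s: %d accepted CP(s), %d excluded, %d regime(s)\n",
              x$patient_id, nrow(x$cps), nrow(x$excluded), nrow(x$regimes)))
  if (nrow(x$cps)) {
    df <- x$cps
    df$timestamp <- format(df$timestamp, tz = "UTC", usetz = TRUE)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Number of accepted change points
#' @param cpset a `changepoint_set`.
#' @return integer count.
#' @export
n_change_points <- function(cpset) nrow(cpset$cps)

#' Fit the final per-regime inertia models
#'
#' After segmentation, each regime is modelled independently with
#' [fit_tv_ar()], giving an inertia curve `f1(t)` that varies smoothly within
#' regimes and jumps at change points. Inertia values above 1 (locally
#' explosive estimates, typically near change points) are flagged, not
#' clamped.
#'
#' @param series a regular [stress_series()].
#' @param cpset the [detect_change_points()] result for the series.
#' @param config a [detector_config()].
#' @return an `inertia_model`: list of per-regime `tvar_model`s plus the
#'   concatenated curve (see [inertia_curve()]).
#' @export
final_inertia_model <- function(series, cpset, config = detector_config()) {
  mv <- modeling_view(series)
  pairs <- build_lag_pairs(mv)
  models <- vector("list", nrow(cpset$regimes))
  rows <- vector("list", nrow(cpset$regimes))
  for (i in seq_len(nrow(cpset$regimes))) {
    rg <- cpset$regimes[i, ]
    sub <- pairs[pairs$t >= rg$start & pairs$t < rg$end, , drop = FALSE]
    if (nrow(sub) < config$min_segment)
      stop(sprintf("regime %d has %d pairs (< min_segment %d); pruning should prevent this",
                   i, nrow(sub), config$min_segment))
    m <- fit_tv_ar(sub, config)
    models[[i]] <- m
    rows[[i]] <- data.frame(epoch = sub$t,
                            timestamp = epoch_time(series, sub$t),
                            f0 = m$intercept_curve, f1 = m$ar_curve,
                            regime_id = i)
  }
  curve <- do.call(rbind, rows)
  curve$flag_gt1 <- curve$f1 > 1
  if (any(curve$flag_gt1))
    warning(sprintf("inertia estimate exceeds 1 at %d epoch(s) (flagged, not clamped)",
                    sum(curve$flag_gt1)))
  structure(list(patient_id = series$patient_id, models = models,
                 curve = curve, cpset = cpset),
            class = "inertia_model")
}

#' Concatenated inertia curve of a final model
#'
#' @param x an [final_inertia_model()] result.
#' @return data frame `epoch`, `timestamp`, `f0`, `f1`, `regime_id`,
#'   `flag_gt1`, suitable for plotting the per-patient inertia trajectory with
#'   change-point markers.
#' @export
inertia_curve <- function(x) x$curve

#' Plot a patient's inertia trajectory with change-point markers
#'
#' Inertia `f1(t)` against epoch, drawn separately per regime so jumps appear
#' as discontinuities, with vertical lines at accepted change points.
#'
#' @param x an `inertia_model`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.inertia_model <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$epoch, cv$f1, type = "n",
                 xlab = "epoch", ylab = "inertia f1(t)",
                 main = sprintf("Stress inertia, patient %s", x$patient_id), ...)
  for (g in split(cv, cv$regime_id))
    graphics::lines(g$epoch, g$f1)
  graphics::abline(v = x$cpset$cps$epoch, lty = 2, col = "grey40")
  graphics::abline(h = 1, lty = 3, col = "red3")
  invisible(x)
}
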