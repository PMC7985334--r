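#' Detector configuration
#'
#' Tuning parameters of the change-point detector. The acceptance threshold on
#' the AIC difference defaults to -15 (a change point is accepted only when
#' the regime-shift model improves AIC by more than 15 units over the gradual
#' model), chosen to keep false positives rare. The remaining parameters
#' control segment admissibility: a regime must contain at least `min_segment`
#' usable lag pairs for stable spline estimation, accepted change points must
#' be at least `min_gap` epochs apart, and candidates within `boundary_margin`
#' epochs of a window edge are not evaluated (changes near boundaries cannot
#' be estimated reliably).
#'
#' @param threshold AIC-difference acceptance threshold, negative (default -15).
#' @param min_segment minimum usable lag pairs per regime (default 50).
#' @param min_gap minimum epochs between accepted change points (default
#'   `min_segment`).
#' @param boundary_margin minimum epochs from a window edge (default
#'   `min_segment`).
#' @param candidate_stride evaluate every `candidate_stride`-th admissible
#'   candidate epoch (default 1 = exhaustive).
#' @param max_depth recursion limit of the binary segmentation (default 12).
#' @param basis_dim spline basis dimension per smooth term (default 10).
#' @param smoothing smoothness selection: `"penalized_ml"` (ML) or
#'   `"cross_validation"` (GCV).
#' @return a `detector_config` list.
#' @export
detector_config <- function(threshold = -15, min_segment = 50,
                            min_gap = min_segment,
                            boundary_margin = min_segment,
                            candidate_stride = 1, max_depth = 12,
                            basis_dim = 10,
                            smoothing = c("penalized_ml", "cross_validation")) {
  smoothing <- match.arg(smoothing)
  if (threshold >= 0) stop("threshold must be negative")
  if (min_segment < 2) stop("min_segment must be >= 2")
  if (candidate_stride < 1) stop("candidate_stride must be >= 1")
  if (basis_dim < 4) stop("basis_dim must be >= 4")
  structure(list(threshold = threshold, min_segment = min_segment,
                 min_gap = min_gap, boundary_margin = boundary_margin,
                 candidate_stride = as.integer(candidate_stride),
                 max_depth = max_depth, basis_dim = basis_dim,
                 smoothing = smoothing),
            class = "detector_config")
}

#' Build the autoregressive lag-pair frame
#'
#' A lag pair (y_{t-1}, y_t) is usable only when both epochs are observed and
#' grid-adjacent; pairs spanning any missing epoch are excluded, so gaps break
#' the AR chain rather than being bridged. `t` is the 0-based epoch index of
#' the response slot.
#'
#' @param series a regular [stress_series()] (any missing-code flavour; all
#'   non-observed codes break adjacency).
#' @param min_pairs minimum number of pairs required (default 1; detection
#'   demands far more, see [detector_config()]).
#' @return a `lag_pairs` data frame with columns `t`, `y_prev`, `y`, carrying
#'   the grid geometry as attributes.
#' @export
build_lag_pairs <- function(series, min_pairs = 1) {
  stopifnot_regular(series)
  obs <- series$missing_code == "observed"
  n <- length(obs)
  ok <- which(obs[-1] & obs[-n]) + 1L          # response slot index (1-based)
  pairs <- data.frame(t = ok - 1L,             # 0-based epoch of response
                      y_prev = series$values[ok - 1L],
                      y = series$values[ok])
  if (nrow(pairs) < min_pairs)
    stop(sprintf("series too short/gappy: %d usable lag pairs (< %d)",
                 nrow(pairs), min_pairs))
  attr(pairs, "epoch_start") <- series$time[1]
  attr(pairs, "epoch_minutes") <- series$epoch_minutes
  attr(pairs, "n_slots") <- n
  attr(pairs, "patient_id") <- series$patient_id
  class(pairs) <- c("lag_pairs", "data.frame")
  pairs
}

# Gaussian log-likelihood at the MLE variance, the common currency for all
# model comparisons here.
gaussian_loglik <- function(rss, n) -n / 2 * (log(2 * pi * rss / n) + 1)

#' Fit the gradual (time-varying) AR(1) model
#'
#' Fits `y_t = f0(t) + f1(t) * y_{t-1} + e_t` with `f0`, `f1` penalized cubic
#' regression splines in the epoch index (mgcv; `basis_dim` knots each, spread
#' over the observed range) and Gaussian errors. `f1(t)` is the time-varying
#' inertia curve. The reported AIC is `-2*loglik + 2*edf` with the Gaussian
#' log-likelihood at the MLE variance and `edf` the trace of the penalized
#' fit's influence matrix — the same currency used for change-point models, so
#' AIC differences are internally consistent.
#'
#' @param pairs a [build_lag_pairs()] frame.
#' @param config a [detector_config()].
#' @return a `tvar_model`: curves `intercept_curve` (f0) and `ar_curve` (f1)
#'   evaluated at the pair epochs, `edf`, `loglik`, `aic`, `residual_sd`, the
#'   underlying mgcv fit, and the selected smoothing parameters.
#' @export
fit_tv_ar <- function(pairs, config = detector_config()) {
  n <- nrow(pairs)
  if (n < config$min_segment)
    stop(sprintf("too few lag pairs (%d < min_segment %d)", n, config$min_segment))
  method <- switch(config$smoothing, penalized_ml = "ML",
                   cross_validation = "GCV.Cp")
  k <- min(config$basis_dim, length(unique(pairs$t)) - 2L)
  if (k < 4) stop("too few distinct epochs for a spline basis")
  df <- data.frame(t = pairs$t, y_prev = pairs$y_prev, y = pairs$y)
  rank_deficient <- FALSE
  if (sd(df$y_prev) < 1e-8) {
    warning("y_prev is constant; falling back to intercept-only smooth")
    rank_deficient <- TRUE
    m <- mgcv::gam(y ~ s(t, bs = "cr", k = k), data = df, method = method)
  } else {
    m <- mgcv::gam(y ~ s(t, bs = "cr", k = k) +
                     s(t, bs = "cr", k = k, by = y_prev),
                   data = df, method = method)
  }
  rss <- sum(residuals(m)^2)
  edf <- sum(m$edf)
  ll <- gaussian_loglik(max(rss, 1e-300), n)
  curves <- eval_curves(m, pairs$t, rank_deficient)
  structure(list(fit = m, t = pairs$t,
                 intercept_curve = curves$f0, ar_curve = curves$f1,
                 edf = edf, loglik = ll, aic = -2 * ll + 2 * edf,
                 residual_sd = sqrt(rss / n), rss = rss, n = n,
                 basis_dim = k, smoothing = config$smoothing, sp = m$sp,
                 rank_deficient = rank_deficient),
            class = "tvar_model")
}

# Evaluate f0(t) and f1(t) from an mgcv fit at epochs tt.
eval_curves <- function(m, tt, rank_deficient = FALSE) {
  if (rank_deficient) {
    nd <- data.frame(t = tt)
    f0 <- as.numeric(predict(m, newdata = nd))
    return(list(f0 = f0, f1 = rep(0, length(tt))))
  }
  nd <- data.frame(t = tt, y_prev = 1)
  tm <- predict(m, newdata = nd, type = "terms")
  icpt <- attr(tm, "constant")
  f0 <- as.numeric(tm[, "s(t)"]) + icpt
  f1 <- as.numeric(tm[, "s(t):y_prev"])
  list(f0 = f0, f1 = f1)
}

#' @export
print.tvar_model <- function(x, ...) {
  cat(sprintf("<tvar_model> n=%d  edf=%.2f  AIC=%.2f  sigma=%.2f\n",
              x$n, x$edf, x$aic, x$residual_sd))
  cat(sprintf("  inertia f1(t): mean %.3f, range [%.3f, %.3f]%s\n",
              mean(x$ar_curve), min(x$ar_curve), max(x$ar_curve),
              if (any(x$ar_curve > 1)) "  [flag: f1 > 1]" else ""))
  invisible(x)
}

# --- fixed-smoothing penalized least squares machinery ---------------------
# The change-point model augments the gradual model's design with two step
# columns and is fitted by penalized least squares at the gradual model's
# smoothing parameters (conditioning on smoothness, as in GAM-based scan
# procedures). These helpers extract the design and total penalty.

lp_design <- function(model) {
  X <- predict(model$fit, type = "lpmatrix")
  p <- ncol(X)
  S <- matrix(0, p, p)
  sp <- model$fit$sp
  k <- 0
  for (sm in model$fit$smooth) {
    for (j in seq_along(sm$S)) {
      k <- k + 1
      idx <- sm$first.para:sm$last.para
      S[idx, idx] <- S[idx, idx] + sp[k] * sm$S[[j]]
    }
  }
  list(X = X, S = S)
}

# Penalized LS fit of [X U] with penalty diag(S, 0); returns coefficients,
# rss and edf (trace of the influence matrix).
penalized_ls_aug <- function(X, S, y, U = NULL) {
  Xa <- if (is.null(U)) X else cbind(X, U)
  q <- ncol(Xa)
  Sa <- matrix(0, q, q)
  Sa[seq_len(ncol(X)), seq_len(ncol(X))] <- S
  XtX <- crossprod(Xa)
  A <- XtX + Sa
  b <- solve(A, crossprod(Xa, y))
  fitted <- as.numeric(Xa %*% b)
  rss <- sum((y - fitted)^2)
  edf <- sum(diag(solve(A, XtX)))
  list(coef = as.numeric(b), rss = rss, edf = edf, fitted = fitted)
}

#' Fit the change-point AR model at a given epoch
#'
#' Augments the gradual model with a regime shift at `cp_epoch`:
#' `y_t = f0(t) + d0*I(t >= cp) + (f1(t) + d1*I(t >= cp)) * y_{t-1} + e_t`,
#' where `d0`, `d1` are free constant shifts in intercept and AR coefficient.
#' The smooths and their smoothing parameters are those of the gradual fit;
#' the augmented model is estimated by penalized least squares, and its AIC
#' uses the same Gaussian likelihood/edf currency as [fit_tv_ar()] (the edf
#' accounts for the two extra parameters through the influence-matrix trace).
#'
#' @param pairs a [build_lag_pairs()] frame.
#' @param cp_epoch candidate change-point epoch (0-based); the shift applies to
#'   responses at `t >= cp_epoch`.
#' @param config a [detector_config()].
#' @param gradual optionally a pre-computed [fit_tv_ar()] on the same pairs.
#' @return a `tvar_cp_model` (also a `tvar_model`) with `delta0`, `delta1`,
#'   `cp_epoch`, and `delta_aic` relative to the gradual model.
#' @export
fit_cp_ar <- function(pairs, cp_epoch, config = detector_config(),
                      gradual = NULL) {
  if (is.null(gradual)) gradual <- fit_tv_ar(pairs, config)
  if (gradual$rank_deficient)
    stop("gradual model is rank deficient; no AR structure to shift")
  n_left <- sum(pairs$t < cp_epoch)
  n_right <- nrow(pairs) - n_left
  if (n_left < config$min_segment || n_right < config$min_segment)
    stop(sprintf(
      "regime too small at cp %d: %d/%d pairs (min_segment %d); a regime cannot hold fewer than min_segment measurements",
      cp_epoch, n_left, n_right, config$min_segment))
  d <- lp_design(gradual)
  step <- as.numeric(pairs$t >= cp_epoch)
  U <- cbind(step = step, step_ar = step * pairs$y_prev)
  fit <- penalized_ls_aug(d$X, d$S, pairs$y, U)
  n <- nrow(pairs)
  ll <- gaussian_loglik(max(fit$rss, 1e-300), n)
  aic <- -2 * ll + 2 * fit$edf
  p <- ncol(d$X)
  delta0 <- fit$coef[p + 1]; delta1 <- fit$coef[p + 2]
  # curves: gradual smooths evaluated from the augmented coefficients
  Xc <- d$X; beta <- fit$coef[seq_len(p)]
  curves <- eval_curves_coef(gradual$fit, pairs$t, beta)
  f0 <- curves$f0 + delta0 * step
  f1 <- curves$f1 + delta1 * step
  structure(list(fit = gradual$fit, t = pairs$t,
                 intercept_curve = f0, ar_curve = f1,
                 edf = fit$edf, loglik = ll, aic = aic,
                 residual_sd = sqrt(fit$rss / n), rss = fit$rss, n = n,
                 basis_dim = gradual$basis_dim, smoothing = gradual$smoothing,
                 sp = gradual$sp, rank_deficient = FALSE,
                 cp_epoch = cp_epoch, delta0 = delta0, delta1 = delta1,
                 delta_aic = aic - gradual$aic, gradual_aic = gradual$aic),
            class = c("tvar_cp_model", "tvar_model"))
}

# Evaluate the smooth curves implied by an arbitrary coefficient vector on the
# gradual model's basis.
eval_curves_coef <- function(m, tt, beta) {
  nd <- data.frame(t = tt, y_prev = 1)
  Xp <- predict(m, newdata = nd, type = "lpmatrix")
  sm <- m$smooth
  idx1 <- sm[[1]]$first.para:sm[[1]]$last.para   # s(t)
  idx2 <- sm[[2]]$first.para:sm[[2]]$last.para   # s(t):y_prev
  f0 <- as.numeric(Xp[, 1, drop = FALSE] %*% beta[1] +
                     Xp[, idx1, drop = FALSE] %*% beta[idx1])
  f1 <- as.numeric(Xp[, idx2, drop = FALSE] %*% beta[idx2])
  list(f0 = f0, f1 = f1)
}

#' AIC difference of the change-point model versus the gradual model
#'
#' Returns `AIC(change-point model) - AIC(gradual model)`; negative values
#' favour the change point. A change point is accepted when the difference
#' falls below the configured threshold (default -15).
#'
#' @inheritParams fit_cp_ar
#' @return numeric AIC difference.
#' @export
delta_aic <- function(pairs, cp_epoch, config = detector_config(),
                      gradual = NULL) {
  fit_cp_ar(pairs, cp_epoch, config, gradual = gradual)$delta_aic
}
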