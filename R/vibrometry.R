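# Laser-vibrometry style analysis: sliding-RMS smoothing, effective response
# amplitude (the dB amount by which the signal-driven response exceeds the
# masker-driven noise floor), the effective interaural vibration amplitude
# difference (IVAD), sigmoid fitting of IVAD vs azimuth, and inversion of
# the fitted curve to a predicted incident sound direction.

#' Centred sliding RMS
#'
#' `out[i]` is the RMS of the window centred at `i`; at the edges the window
#' shrinks to the valid part of the series (so constant inputs map to
#' constants). Length is preserved. Implemented with cumulative sums, O(n).
#'
#' @param x Numeric vector (or [pressure_trace()]).
#' @param window Window length in samples (2 <= window <= length(x)).
#' @return Numeric vector of the same length as `x`.
#' @export
sliding_rms <- function(x, window) {
  x <- trace_samples(x)
  n <- length(x)
  if (window < 2 || window > n)
    stop("sliding_rms: window must be in [2, length(x)]")
  h_lo <- floor((window - 1) / 2)
  h_hi <- window - 1 - h_lo
  i <- seq_len(n)
  lo <- pmax(1, i - h_lo)
  hi <- pmin(n, i + h_hi)
  cs <- c(0, cumsum(x^2))
  sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}

# Centred sliding mean with shrink-to-valid edges (for velocity smoothing).
sliding_mean <- function(x, window) {
  n <- length(x)
  if (window <= 1) return(x)
  window <- min(window, n)
  h_lo <- floor((window - 1) / 2)
  h_hi <- window - 1 - h_lo
  i <- seq_len(n)
  lo <- pmax(1, i - h_lo)
  hi <- pmin(n, i + h_hi)
  cs <- c(0, cumsum(x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Window schedule for the repeated-pulse vibrometry protocol
#'
#' For signal pulses repeated at 400 ms intervals: 30 ms signal segments at
#' each pulse onset, and 30 ms masker segments in the middle of the
#' interpulse interval (200 ms after pulse onset).
#'
#' @param onsets_s Pulse onset times in seconds.
#' @param sig_ms Signal-segment length in ms (default 30).
#' @param gap_ms Delay from pulse onset to the masker segment in ms
#'   (default 200).
#' @param mask_ms Masker-segment length in ms (default 30).
#' @return List with `signal` and `masker`, each a 2-column matrix of
#'   window start/end times in seconds.
#' @export
pulse_protocol_windows <- function(onsets_s, sig_ms = 30, gap_ms = 200,
                                   mask_ms = 30) {
  win <- function(from, to) matrix(c(from, to), ncol = 2)
  list(signal = win(onsets_s, onsets_s + sig_ms / 1000),
       masker = win(onsets_s + gap_ms / 1000,
                    onsets_s + (gap_ms + mask_ms) / 1000))
}

#' Window schedule for a trill embedded in a masker
#'
#' For a continuous trill the signal epoch is the signal+masker interval and
#' the noise-floor epoch is the masker-alone second leading up to signal
#' onset.
#'
#' @param signal_onset_s Signal onset time (s).
#' @param signal_dur_s Signal duration (s, default 2).
#' @param masker_lead_s Length of the masker-alone epoch before signal onset
#'   used as the noise floor (default 1).
#' @return List with `signal` and `masker` 2-column window matrices.
#' @export
trill_windows <- function(signal_onset_s, signal_dur_s = 2, masker_lead_s = 1) {
  list(signal = matrix(c(signal_onset_s, signal_onset_s + signal_dur_s),
                       ncol = 2),
       masker = matrix(c(signal_onset_s - masker_lead_s, signal_onset_s),
                       ncol = 2))
}

#' Effective response amplitude
#'
#' The per-iteration effective amplitude is the dB difference between the
#' RMS in a signal(+masker) window and the RMS in the paired masker-alone
#' window: 20*log10(RMS_signal / RMS_masker). This is the magnitude of the
#' response to the target signal above the masker-driven noise floor. The
#' summary value is the arithmetic mean of the per-iteration dB values.
#'
#' @param trace A [pressure_trace()], one side of `tympanal_traces`, or a
#'   numeric vector.
#' @param fs_hz Sample rate (taken from the trace if available).
#' @param signal_windows 2-column matrix of signal window start/end times (s).
#' @param masker_windows 2-column matrix of masker window start/end times (s);
#'   either one row per signal window or a single row reused for all.
#' @param ear Optional ear label (`"left"`, `"right"`, `"ipsi"`, `"contra"`).
#' @return An object of class `effective_amplitude` with `value_db` (mean)
#'   and `per_iteration_db`.
#' @export
effective_amplitude <- function(trace, fs_hz = NULL, signal_windows,
                                masker_windows, ear = NA_character_) {
  if (inherits(trace, "pressure_trace")) {
    fs_hz <- trace$fs_hz
    x <- trace$samples
  } else x <- as.numeric(trace)
  if (is.null(fs_hz)) stop("effective_amplitude: fs_hz required")
  signal_windows <- matrix(signal_windows, ncol = 2)
  masker_windows <- matrix(masker_windows, ncol = 2)
  k <- nrow(signal_windows)
  if (nrow(masker_windows) == 1 && k > 1)
    masker_windows <- masker_windows[rep(1, k), , drop = FALSE]
  if (nrow(masker_windows) != k)
    stop("effective_amplitude: window counts differ")
  win_rms <- function(w) {
    idx <- (round(w[1] * fs_hz) + 1):round(w[2] * fs_hz)
    if (idx[1] < 1 || idx[length(idx)] > length(x))
      stop("effective_amplitude: window outside trace")
    rms(x[idx])
  }
  per <- vapply(seq_len(k), function(i) {
    rs <- win_rms(signal_windows[i, ])
    rm_ <- win_rms(masker_windows[i, ])
    if (rm_ == 0) stop("effective_amplitude: zero-RMS masker window")
    20 * log10(rs / rm_)
  }, numeric(1))
  structure(list(value_db = mean(per), per_iteration_db = per, ear = ear),
            class = "effective_amplitude")
}

#' @export
print.effective_amplitude <- function(x, ...) {
  cat(sprintf("effective_amplitude (%s): %.3f dB (mean of %d iterations)\n",
              x$ear, x$value_db, length(x$per_iteration_db)))
  invisible(x)
}

#' Effective interaural vibration amplitude difference (IVAD)
#'
#' The difference in effective response amplitude between the ears. With
#' the contra/ipsi labelling (re the masker), a positive value means the
#' masker-contralateral ear dominates, biasing the percept away from the
#' masker.
#'
#' @param contra [effective_amplitude()] of the masker-contralateral ear
#'   (or a number).
#' @param ipsi [effective_amplitude()] of the masker-ipsilateral ear (or a
#'   number).
#' @param snr_db Optional broadcast SNR label.
#' @return An object of class `ivad_measurement` with `value_db`.
#' @export
compute_ivad <- function(contra, ipsi, snr_db = NA_real_) {
  val <- function(e) if (inherits(e, "effective_amplitude")) e$value_db else e
  structure(list(value_db = val(contra) - val(ipsi), snr_db = snr_db),
            class = "ivad_measurement")
}

#' @export
print.ivad_measurement <- function(x, ...) {
  cat(sprintf("ivad_measurement: %.3f dB (SNR %s dB)\n", x$value_db,
              format(x$snr_db)))
  invisible(x)
}

# 4-parameter logistic used for both IVAD-vs-azimuth and d_a-vs-level fits.
logistic4 <- function(par, x) {
  par[1] + par[2] / (1 + exp(-(x - par[3]) / par[4]))
}

#' Fit a sigmoid (4-parameter logistic) by derivative-free least squares
#'
#' y(x) = y0 + a / (1 + exp(-(x - x0)/b)), fitted by Nelder-Mead simplex
#' minimization of the residual sum of squares with multiple deterministic
#' starts; the best-RSS solution wins. Convergence is declared when
#' repeated restarts change the RSS by less than `tol`.
#'
#' @param xs,ys Numeric data (>= 4 points spanning both sides of the
#'   inflection for a meaningful fit).
#' @param n_starts Number of distinct starting simplices (>= 5).
#' @param tol Absolute RSS-change tolerance for convergence (default 1e-8).
#' @return An object of class `fitted_sigmoid` with elements `par`
#'   (y0, a, x0, b), `rss`, `converged`, and `xrange`. Degenerate (constant)
#'   data yield `converged = FALSE` without an error.
#' @export
fit_sigmoid <- function(xs, ys, n_starts = 7, tol = 1e-8) {
  stopifnot(length(xs) == length(ys), length(xs) >= 4)
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  xr <- range(xs)
  out <- structure(list(par = c(y0 = ys[1], a = 0, x0 = mean(xr), b = diff(xr) / 5),
                        rss = NA_real_, converged = FALSE, xrange = xr),
                   class = "fitted_sigmoid")
  if (diff(range(ys)) == 0) {
    out$rss <- 0
    return(out)  # fit-failure flag: constant data, slope unidentifiable
  }
  rss_fn <- function(p) {
    r <- ys - logistic4(p, xs)
    sum(r * r)
  }
  span <- diff(range(ys))
  base <- c(min(ys), span * sign(stats::cor(xs, ys)),
            mean(xr), diff(xr) / 5)
  if (base[2] < 0) base[1] <- max(ys)
  # deterministic start perturbations (no RNG: fits are reproducible)
  mults <- rbind(c(1, 1, 1, 1),
                 c(1, 1, 1, 0.3),
                 c(1, 1, 1, 3),
                 c(1, 1.5, 1, 1),
                 c(1, 0.7, 1, 0.5),
                 c(1, 1, 1, 10),
                 c(1, 2, 1, 0.15))
  shifts <- cbind(0, 0, c(0, 0, 0, -diff(xr) / 4, diff(xr) / 4, 0, 0), 0)
  n_starts <- max(5, n_starts)
  best <- NULL
  for (s in seq_len(min(n_starts, nrow(mults)))) {
    p0 <- base * mults[s, ] + shifts[s, ]
    fit <- stats::optim(p0, rss_fn, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    # polish by restarting until the RSS stops improving
    for (r in 1:8) {
      fit2 <- stats::optim(fit$par, rss_fn, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-12))
      if (fit$value - fit2$value < tol) { fit <- fit2; break }
      fit <- fit2
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  out$par <- stats::setNames(best$par, c("y0", "a", "x0", "b"))
  out$rss <- best$value
  out$converged <- TRUE
  out
}

#' Evaluate a fitted sigmoid
#'
#' @param object A `fitted_sigmoid`.
#' @param x Numeric values at which to evaluate the curve.
#' @param ... Unused.
#' @return Fitted values.
#' @export
predict.fitted_sigmoid <- function(object, x, ...) {
  logistic4(object$par, x)
}

#' @export
print.fitted_sigmoid <- function(x, ...) {
  cat(sprintf(
    "fitted_sigmoid: y0 %.4g, a %.4g, x0 %.4g, b %.4g; rss %.3g; %s\n",
    x$par[1], x$par[2], x$par[3], x$par[4], x$rss,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

sigmoid_monotone <- function(fit) {
  g <- seq(fit$xrange[1], fit$xrange[2], length.out = 201)
  d <- diff(predict(fit, g))
  all(d > 0) || all(d < 0)
}

#' Predict the incident sound direction from an IVAD measurement
#'
#' Numerically inverts a fitted, monotone IVAD-vs-azimuth curve (bisection
#' via [stats::uniroot()]). IVAD values beyond the fitted curve's range are
#' clamped to the range endpoints with a warning.
#'
#' @param ivad An [compute_ivad()] result or a numeric IVAD in dB.
#' @param fit A `fitted_sigmoid` of IVAD (dB) against azimuth (deg), or a
#'   directionality curve (then inverted analytically).
#' @return Predicted azimuth(s) in degrees.
#' @export
predict_direction <- function(ivad, fit) {
  y <- if (inherits(ivad, "ivad_measurement")) ivad$value_db else as.numeric(ivad)
  if (inherits(fit, c("directionality_curve", "directionality_table")))
    return(azimuth_at(fit, y))
  stopifnot(inherits(fit, "fitted_sigmoid"))
  if (!fit$converged) stop("predict_direction: fit did not converge")
  if (!sigmoid_monotone(fit))
    stop("predict_direction: fitted curve is not monotone over its range")
  f <- function(x) predict(fit, x)
  ylo <- f(fit$xrange[1]); yhi <- f(fit$xrange[2])
  lo <- min(ylo, yhi); hi <- max(ylo, yhi)
  vapply(y, function(yy) {
    if (yy <= lo || yy >= hi) {
      if (yy < lo || yy > hi)
        warning("predict_direction: IVAD beyond fitted range; clamping")
      return(if ((yy <= lo) == (ylo <= yhi)) fit$xrange[1] else fit$xrange[2])
    }
    stats::uniroot(function(x) f(x) - yy, interval = fit$xrange,
                   tol = 1e-10)$root
  }, numeric(1))
}
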