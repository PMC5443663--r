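# Auditory-nerve masked-threshold analysis: impulse detection at a 3 SD
# threshold above the quiet-epoch RMS, windowed response measures (impulse
# counts or window RMS over 40 ms), the standard separation statistic d_a,
# and masked thresholds from a fitted sigmoid crossing d_a = 1.

#' Detect impulses in an extracellular voltage trace
#'
#' The detection threshold is the RMS of a stimulus-free (quiet) epoch plus
#' three standard deviations of that epoch; events are upward crossings of
#' the threshold with a 1 ms dead time.
#'
#' @param v Numeric voltage trace (or [pressure_trace()]).
#' @param fs_hz Sample rate (taken from the trace if available).
#' @param quiet_s Length-2 numeric: start/end (s) of the quiet epoch
#'   (>= 100 ms).
#' @param dead_ms Dead time in ms (default 1).
#' @param sd_mult Multiplier on the quiet-epoch SD (default 3).
#' @param channel Channel label for the returned spike train.
#' @return A [spike_train()].
#' @export
detect_impulses <- function(v, fs_hz = NULL, quiet_s, dead_ms = 1,
                            sd_mult = 3, channel = NA_character_) {
  if (inherits(v, "pressure_trace")) {
    fs_hz <- v$fs_hz
    v <- v$samples
  }
  v <- as.numeric(v)
  if (is.null(fs_hz)) stop("detect_impulses: fs_hz required")
  qidx <- max(1, round(quiet_s[1] * fs_hz)):min(length(v), round(quiet_s[2] * fs_hz))
  if (length(qidx) < round(0.1 * fs_hz))
    stop("detect_impulses: quiet epoch must be at least 100 ms")
  q <- v[qidx]
  thr <- rms(q) + sd_mult * stats::sd(q)
  if (thr == 0) thr <- .Machine$double.eps
  up <- which(v[-1] >= thr & v[-length(v)] < thr) + 1
  times <- enforce_refractory((up - 1) / fs_hz, dead_ms / 1000)
  spike_train(times, channel)
}

#' Windowed response sample
#'
#' Per-sweep response measures (impulse counts or window RMS) collected in
#' a fixed 40 ms window under one stimulus condition.
#'
#' @param values One measure per sweep.
#' @param condition `"masker_alone"` or `"signal_plus_masker"`.
#' @param level_db The varied level (masker or signal, per protocol).
#' @param measure `"impulse_count"` or `"window_rms"`.
#' @param window_s Window length in seconds (default 0.040).
#' @return An object of class `response_sample`.
#' @export
response_sample <- function(values,
                            condition = c("masker_alone", "signal_plus_masker"),
                            level_db = NA_real_,
                            measure = c("impulse_count", "window_rms"),
                            window_s = 0.040) {
  condition <- match.arg(condition)
  measure <- match.arg(measure)
  if (length(values) < 2)
    stop("response_sample: need at least 2 sweeps")
  structure(list(values = as.numeric(values), condition = condition,
                 level_db = level_db, measure = measure, window_s = window_s),
            class = "response_sample")
}

#' Standard separation d_a between response distributions
#'
#' d_a compares the response distribution with the signal present to the
#' masker-alone distribution without assuming equal variances:
#' d_a = (mu_sn - mu_n) / sqrt((sigma2_sn + sigma2_n) / 2) in the default
#' pooled form. A variant with a minus in the radicand is available as
#' `form = "printed"`; it is undefined (flagged) when the radicand is
#' non-positive.
#'
#' @param sample_n Masker-alone values (numeric vector or
#'   [response_sample()]).
#' @param sample_sn Signal-plus-masker values.
#' @param form `"pooled"` (default) or `"printed"`.
#' @return An object of class `standard_separation` with elements `d_a`,
#'   `form`, and `undefined` (TRUE when the printed form's radicand <= 0,
#'   or `d_a` infinite when the pooled variance is zero with a nonzero mean
#'   difference).
#' @export
standard_separation <- function(sample_n, sample_sn,
                                form = c("pooled", "printed")) {
  form <- match.arg(form)
  val <- function(s) if (inherits(s, "response_sample")) s$values else as.numeric(s)
  xn <- val(sample_n)
  xsn <- val(sample_sn)
  if (length(xn) < 2 || length(xsn) < 2)
    stop("standard_separation: need at least 2 sweeps per sample")
  dm <- mean(xsn) - mean(xn)
  rad <- if (form == "pooled") (stats::var(xsn) + stats::var(xn)) / 2
         else (stats::var(xsn) - stats::var(xn)) / 2
  undefined <- FALSE
  if (rad <= 0) {
    if (form == "printed") {
      undefined <- TRUE
      d <- NA_real_
    } else {
      # zero pooled variance: identical constants give 0, otherwise infinite
      d <- if (dm == 0) 0 else Inf * sign(dm)
      undefined <- is.infinite(d)
    }
  } else d <- dm / sqrt(rad)
  structure(list(d_a = d, form = form, undefined = undefined,
                 mu_n = mean(xn), mu_sn = mean(xsn),
                 var_n = stats::var(xn), var_sn = stats::var(xsn)),
            class = "standard_separation")
}

#' @export
print.standard_separation <- function(x, ...) {
  cat(sprintf("standard_separation (%s form): d_a = %s%s\n", x$form,
              format(x$d_a, digits = 4),
              if (x$undefined) " [undefined]" else ""))
  invisible(x)
}

#' Masked threshold from a fitted d_a curve
#'
#' Fits a monotone sigmoid to d_a against the swept level (signal or masker,
#' whichever the protocol varied) and locates the level at which the fitted
#' curve crosses the criterion (d_a = 1 by convention) by bisection.
#'
#' @param level_db Swept levels in dB.
#' @param d_a d_a values (numeric, or a list of [standard_separation()]
#'   results). Non-finite values are dropped before fitting.
#' @param criterion Threshold criterion on d_a (default 1.0).
#' @param ear Optional ear label (`"ipsi"` / `"contra"` re the masker).
#' @return An object of class `masked_threshold` with `threshold_db` (NA
#'   with `out_of_range = TRUE` if the fitted curve does not cross the
#'   criterion within the tested range), the `fit`, and the crossing
#'   direction.
#' @export
masked_threshold <- function(level_db, d_a, criterion = 1.0,
                             ear = NA_character_) {
  if (is.list(d_a))
    d_a <- vapply(d_a, function(s) s$d_a, numeric(1))
  keep <- is.finite(d_a) & is.finite(level_db)
  xs <- level_db[keep]
  ys <- d_a[keep]
  if (length(xs) < 4)
    stop("masked_threshold: need at least 4 finite d_a points")
  fit <- fit_sigmoid(xs, ys)
  out <- structure(list(threshold_db = NA_real_, criterion = criterion,
                        ear = ear, fit = fit, out_of_range = FALSE),
                   class = "masked_threshold")
  g <- seq(min(xs), max(xs), length.out = 512)
  fg <- predict(fit, g) - criterion
  sgn <- sign(fg)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flip)) {
    if (any(fg == 0)) {
      out$threshold_db <- g[which(fg == 0)[1]]
    } else {
      out$out_of_range <- TRUE
    }
    return(out)
  }
  i <- flip[1]
  out$threshold_db <- stats::uniroot(function(x) predict(fit, x) - criterion,
                                     interval = c(g[i], g[i + 1]),
                                     tol = 1e-10)$root
  out
}

#' @export
print.masked_threshold <- function(x, ...) {
  if (x$out_of_range)
    cat(sprintf("masked_threshold (%s): no d_a = %g crossing in range\n",
                x$ear, x$criterion))
  else
    cat(sprintf("masked_threshold (%s): %.2f dB at d_a = %g\n",
                x$ear, x$threshold_db, x$criterion))
  invisible(x)
}

#' Synthesize an extracellular voltage trace from a spike train
#'
#' Places a brief biphasic spike waveform at each event time and adds
#' Gaussian recording noise; used to exercise the impulse-detection path on
#' known ground truth.
#'
#' @param spikes A [spike_train()] (or numeric times in seconds).
#' @param fs_hz Sample rate in Hz.
#' @param dur_s Trace duration in seconds.
#' @param spike_amp Peak spike amplitude (default 1).
#' @param noise_sd Recording-noise SD (default 0.05).
#' @param spike_ms Spike waveform duration in ms (default 1).
#' @param seed Optional seed for the noise.
#' @return A [pressure_trace()] holding the voltage series.
#' @export
simulate_nerve_voltage <- function(spikes, fs_hz = 44100, dur_s,
                                   spike_amp = 1, noise_sd = 0.05,
                                   spike_ms = 1, seed = NULL) {
  times <- if (inherits(spikes, "spike_train")) spikes$times_s else as.numeric(spikes)
  n <- round(dur_s * fs_hz)
  v <- with_seed(seed, stats::rnorm(n, sd = noise_sd))
  nw <- max(4, round(spike_ms / 1000 * fs_hz))
  tt <- seq(0, 1, length.out = nw)
  wave <- spike_amp * sin(2 * pi * tt) * exp(-3 * tt)   # biphasic, decaying
  wave <- wave / max(abs(wave)) * spike_amp
  for (t0 in times) {
    idx <- round(t0 * fs_hz) + seq_len(nw)
    ok <- idx >= 1 & idx <= n
    v[idx[ok]] <- v[idx[ok]] + wave[ok]
  }
  pressure_trace(v, fs_hz)
}
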