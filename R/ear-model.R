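# Generative model of the mechanically coupled ears and auditory afferents.
# The intertympanal bridge converts sub-microsecond acoustic ITDs into large
# mechanical interaural amplitude differences; here that directionality is
# summarized by an antisymmetric sigmoid mapping incident azimuth to the
# interaural vibration amplitude difference (IVAD, dB). The difference is
# split symmetrically between the ears (+IVAD/2 on the source-ipsilateral
# side), which is sufficient because every downstream analysis uses
# interaural differences only. Mechanical ITDs are not modelled.

#' Parametric tympanal directionality curve
#'
#' IVAD(theta) = max_ivad_db * (2 / (1 + exp(-theta / slope_deg)) - 1),
#' an antisymmetric sigmoid: zero at the midline, monotone increasing,
#' saturating at +/- max_ivad_db. Positive azimuth (right) gives a larger
#' right-ear response.
#'
#' @param max_ivad_db Saturation amplitude in dB (default 10).
#' @param slope_deg Sigmoid width in degrees (default 30).
#' @return An object of class `directionality_curve`.
#' @export
directionality_curve <- function(max_ivad_db = 10, slope_deg = 30) {
  stopifnot(max_ivad_db > 0, slope_deg > 0)
  structure(list(max_ivad_db = max_ivad_db, slope_deg = slope_deg),
            class = "directionality_curve")
}

#' Tabulated directionality curve
#'
#' Builds a directionality curve from measured (azimuth, IVAD) pairs, e.g.
#' a digitized published measurement, by monotone linear interpolation.
#'
#' @param azimuth_deg Azimuths in degrees (strictly increasing after sorting).
#' @param ivad_db IVAD values in dB (must be non-decreasing in azimuth).
#' @return An object of class `directionality_table`.
#' @export
directionality_table <- function(azimuth_deg, ivad_db) {
  o <- order(azimuth_deg)
  azimuth_deg <- azimuth_deg[o]
  ivad_db <- ivad_db[o]
  if (any(diff(azimuth_deg) <= 0))
    stop("directionality_table: azimuths must be distinct")
  if (any(diff(ivad_db) < 0))
    stop("directionality_table: IVAD must be non-decreasing in azimuth")
  structure(list(azimuth_deg = azimuth_deg, ivad_db = ivad_db),
            class = "directionality_table")
}

#' Read a directionality table from a 2-column delimited file
#'
#' @param path Path to a whitespace/comma-delimited file with columns
#'   azimuth_deg, ivad_db (header optional).
#' @return A [directionality_table()].
#' @export
read_directionality_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "",
                         comment.char = "#", fill = FALSE)
  if (!is.numeric(d[[1]]))  # no header after all
    d <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#")
  directionality_table(d[[1]], d[[2]])
}

#' Evaluate a directionality curve
#'
#' @param curve A [directionality_curve()] or [directionality_table()].
#' @param azimuth_deg Azimuth(s) in degrees.
#' @return IVAD in dB (right-ear minus left-ear response).
#' @export
ivad_at <- function(curve, azimuth_deg) UseMethod("ivad_at")

#' @export
ivad_at.directionality_curve <- function(curve, azimuth_deg) {
  curve$max_ivad_db * (2 / (1 + exp(-azimuth_deg / curve$slope_deg)) - 1)
}

#' @export
ivad_at.directionality_table <- function(curve, azimuth_deg) {
  stats::approx(curve$azimuth_deg, curve$ivad_db, xout = azimuth_deg,
                rule = 2)$y
}

#' Invert a directionality curve
#'
#' Maps an IVAD back to the incident azimuth. Values beyond the curve's
#' range are clamped to the range endpoints with a warning.
#'
#' @param curve A [directionality_curve()] or [directionality_table()].
#' @param ivad_db IVAD value(s) in dB.
#' @return Azimuth(s) in degrees.
#' @export
azimuth_at <- function(curve, ivad_db) UseMethod("azimuth_at")

#' @export
azimuth_at.directionality_curve <- function(curve, ivad_db) {
  r <- ivad_db / curve$max_ivad_db
  out <- numeric(length(r))
  clamped <- abs(r) >= 1
  if (any(clamped)) {
    warning("azimuth_at: IVAD beyond curve range; clamping to +/-180 deg")
    out[clamped] <- sign(r[clamped]) * 180
  }
  out[!clamped] <- curve$slope_deg * log((1 + r[!clamped]) / (1 - r[!clamped]))
  pmin(pmax(out, -180), 180)
}

#' @export
azimuth_at.directionality_table <- function(curve, ivad_db) {
  lo <- min(curve$ivad_db); hi <- max(curve$ivad_db)
  if (any(ivad_db < lo | ivad_db > hi))
    warning("azimuth_at: IVAD beyond table range; clamping")
  ivad_db <- pmin(pmax(ivad_db, lo), hi)
  stats::approx(curve$ivad_db, curve$azimuth_deg, xout = ivad_db,
                rule = 2, ties = mean)$y
}

#' Ear gain model
#'
#' Splits the directionality curve symmetrically between the ears:
#' the right-ear gain is +IVAD(theta)/2 dB and the left-ear gain is
#' -IVAD(theta)/2 dB, so the interaural difference equals IVAD(theta)
#' exactly. Additive Gaussian measurement noise models the vibrometer /
#' recording noise floor.
#'
#' @param curve A directionality curve (default [directionality_curve()]).
#' @param meas_noise_db Level of the additive measurement-noise floor in dB
#'   re the package reference; `NULL` disables noise. Default 30 dB
#'   (40 dB below a 70 dB source).
#' @return An object of class `ear_gain_model`.
#' @export
ear_gain_model <- function(curve = directionality_curve(),
                           meas_noise_db = 30) {
  structure(list(curve = curve, meas_noise_db = meas_noise_db),
            class = "ear_gain_model")
}

ear_gain_db <- function(model, azimuth_deg, ear = c("left", "right")) {
  ear <- match.arg(ear)
  half <- ivad_at(model$curve, azimuth_deg) / 2
  if (ear == "right") half else -half
}

#' Render a scene through the ear model into tympanal vibration traces
#'
#' Each ear's trace is the sum of the source traces scaled by that ear's
#' direction-dependent linear gain, plus Gaussian measurement noise. A
#' single frontal source drives both ears identically (up to noise); a
#' lateral masker drives the masker-ipsilateral ear harder, raising its
#' noise floor.
#'
#' @param scene A `scene_render` from [assemble_scene()].
#' @param model An [ear_gain_model()].
#' @param seed Optional integer seed for the measurement noise.
#' @return An object of class `tympanal_traces` with elements `left`,
#'   `right` (numeric) and `fs_hz`.
#' @export
render_tympanal <- function(scene, model = ear_gain_model(), seed = NULL) {
  stopifnot(inherits(scene, "scene_render"), inherits(model, "ear_gain_model"))
  n <- scene$n
  left <- numeric(n)
  right <- numeric(n)
  for (i in seq_along(scene$traces)) {
    th <- scene$azimuths_deg[i]
    left <- left + 10^(ear_gain_db(model, th, "left") / 20) * scene$traces[[i]]
    right <- right + 10^(ear_gain_db(model, th, "right") / 20) * scene$traces[[i]]
  }
  if (!is.null(model$meas_noise_db)) {
    amp <- db_to_amp(model$meas_noise_db)
    noise <- with_seed(seed, stats::rnorm(2 * n, sd = amp))
    left <- left + noise[seq_len(n)]
    right <- right + noise[n + seq_len(n)]
  }
  structure(list(left = left, right = right, fs_hz = scene$fs_hz),
            class = "tympanal_traces")
}

#' @export
print.tympanal_traces <- function(x, ...) {
  cat(sprintf(
    "tympanal_traces: %d samples at %g Hz; rms L %.4g, R %.4g (%+.2f dB)\n",
    length(x$left), x$fs_hz, rms(x$left), rms(x$right),
    20 * log10(rms(x$right) / rms(x$left))))
  invisible(x)
}

#' Afferent response specification
#'
#' Type I afferents mark each sound-pulse onset with a single spike followed
#' by a refractory period of about 4 ms; Type II respond with several onset
#' spikes. (Type III tonic units are a minority and are not modelled.)
#'
#' @param type `"I"` or `"II"`.
#' @param refractory_ms Dead time after a spike in ms (default 4).
#' @param n_onset_spikes Spikes per threshold crossing; default 1 for Type I,
#'   3 for Type II. Intra-burst spikes are spaced by the refractory period.
#' @param threshold_mult Envelope threshold as a multiple of the quiet-epoch
#'   RMS (default 3, mirroring the neural impulse-detection rule).
#' @param jitter_ms SD of Gaussian spike-time jitter in ms (default 0.2).
#' @param env_window_ms Sliding-RMS window of the fast envelope in ms
#'   (default 3). Short against the 10 ms pulses, but long enough that the
#'   envelope of band-limited noise is not so volatile that masker-driven
#'   crossings saturate the refractory limit.
#' @param adapt_mult Adaptive-floor multiplier (default 1.3). Sustained
#'   noise sets a noise floor above which a signal-driven increment is
#'   required to fire: the instantaneous threshold is the larger of the
#'   quiet-epoch term and `adapt_mult` times a slow running envelope.
#'   Without this the unit would spike once at masker onset and then stay
#'   silent for any sustained masker. Set to `Inf` to disable.
#' @param adapt_window_ms Window of the slow running envelope in ms
#'   (default 200, long against the 10 ms pulses it must not track).
#' @return An object of class `afferent_spec`.
#' @export
afferent_spec <- function(type = c("I", "II"), refractory_ms = 4,
                          n_onset_spikes = NULL, threshold_mult = 3,
                          jitter_ms = 0.2, env_window_ms = 3,
                          adapt_mult = 1.5, adapt_window_ms = 200) {
  type <- match.arg(type)
  if (refractory_ms <= 0) stop("afferent_spec: refractory_ms must be positive")
  if (is.null(n_onset_spikes)) n_onset_spikes <- if (type == "I") 1L else 3L
  structure(list(type = type, refractory_ms = refractory_ms,
                 n_onset_spikes = as.integer(n_onset_spikes),
                 threshold_mult = threshold_mult, jitter_ms = jitter_ms,
                 env_window_ms = env_window_ms, adapt_mult = adapt_mult,
                 adapt_window_ms = adapt_window_ms),
            class = "afferent_spec")
}

#' A sorted spike train
#'
#' @param times_s Event times in seconds (sorted strictly increasing).
#' @param channel `"left"` or `"right"` (optional label).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times_s, channel = NA_character_) {
  times_s <- as.numeric(times_s)
  if (is.unsorted(times_s, strictly = TRUE))
    stop("spike_train: times must be strictly increasing")
  structure(list(times_s = times_s, channel = channel), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train (%s): %d events%s\n",
              x$channel, length(x$times_s),
              if (length(x$times_s)) sprintf(" in [%.4f, %.4f] s",
                                             min(x$times_s), max(x$times_s))
              else ""))
  invisible(x)
}

# Enforce a dead time on sorted candidate event times.
enforce_refractory <- function(times, refractory_s) {
  keep <- numeric(0)
  last <- -Inf
  for (t in times) {
    if (t - last >= refractory_s) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep
}

#' Simulate onset-phasic afferent spikes from a vibration trace
#'
#' The envelope is a 1 ms sliding RMS of the trace; events occur at upward
#' crossings of a threshold set to a multiple of the quiet-epoch RMS, with
#' `n_onset_spikes` per crossing and an absolute dead time between all
#' spikes. Stochastic fluctuations of a noise-driven envelope around the
#' threshold naturally yield irregular spiking during masker-alone epochs.
#'
#' @param trace A [pressure_trace()], `tympanal_traces` side, or numeric
#'   vector.
#' @param fs_hz Sample rate (ignored if `trace` is a [pressure_trace()]).
#' @param quiet_s Length-2 numeric: start/end (s) of a stimulus-free epoch
#'   used to calibrate the threshold.
#' @param spec An [afferent_spec()].
#' @param seed Optional seed for spike-time jitter.
#' @param channel Channel label carried into the spike train.
#' @return A [spike_train()].
#' @export
spikes_from_trace <- function(trace, fs_hz = NULL, quiet_s, spec = afferent_spec(),
                              seed = NULL, channel = NA_character_) {
  if (inherits(trace, "pressure_trace")) {
    fs_hz <- trace$fs_hz
    x <- trace$samples
  } else x <- as.numeric(trace)
  if (is.null(fs_hz)) stop("spikes_from_trace: fs_hz required")
  qidx <- max(1, round(quiet_s[1] * fs_hz)):min(length(x), round(quiet_s[2] * fs_hz))
  if (length(qidx) < 2) stop("spikes_from_trace: empty quiet epoch")
  env <- sliding_rms(x, max(2, round(spec$env_window_ms / 1000 * fs_hz)))
  thr0 <- spec$threshold_mult * rms(x[qidx])
  if (thr0 == 0) thr0 <- .Machine$double.eps
  thr <- rep(thr0, length(env))
  if (is.finite(spec$adapt_mult)) {
    slow <- sliding_rms(x, max(2, round(spec$adapt_window_ms / 1000 * fs_hz)))
    thr <- pmax(thr, spec$adapt_mult * slow)
  }
  n_env <- length(env)
  up <- which(env[-1] >= thr[-1] & env[-n_env] < thr[-n_env]) + 1
  onset_times <- (up - 1) / fs_hz
  refr <- spec$refractory_ms / 1000
  times <- numeric(0)
  for (t0 in onset_times) {
    burst <- t0 + (seq_len(spec$n_onset_spikes) - 1) * refr
    times <- c(times, burst)
  }
  times <- enforce_refractory(sort(times), refr)
  if (spec$jitter_ms > 0 && length(times)) {
    times <- times + with_seed(seed, stats::rnorm(length(times),
                                                  sd = spec$jitter_ms / 1000))
    times <- enforce_refractory(sort(times), refr)
  }
  spike_train(times, channel)
}

#' Map an effective interaural amplitude difference to a heading
#'
#' The fly steers toward the ear with the larger effective amplitude: the
#' heading is the azimuth at which the directionality curve produces the
#' given interaural difference (or a linear gain if no curve is supplied).
#' Antisymmetric, with heading(0) = 0.
#'
#' @param ivad_effective_db Signed effective interaural amplitude difference
#'   (right minus left), dB.
#' @param curve Optional directionality curve to invert.
#' @param gain_deg_per_db Linear gain used when no curve is given
#'   (default 5 deg/dB).
#' @return Heading in degrees (right-positive).
#' @export
simulate_heading <- function(ivad_effective_db, curve = NULL,
                             gain_deg_per_db = 5) {
  stopifnot(all(is.finite(ivad_effective_db)))
  if (is.null(curve)) return(gain_deg_per_db * ivad_effective_db)
  azimuth_at(curve, ivad_effective_db)
}
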