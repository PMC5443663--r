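# Stimulus synthesis: pulsed trills, band-limited noise maskers, and timed
# multi-speaker scenes. The standard target signal is a synthetic cricket
# trill: 10 ms tonal pulses at 5 kHz with 1 ms linear on/off ramps, repeated
# at 50 pulses/s for 2 s. The standard masker is a 4 s burst of ~2-7 kHz
# band-limited Gaussian noise.

#' Specification of a pulsed trill (synthetic cricket song)
#'
#' @param carrier_hz Carrier frequency in Hz (default 5000).
#' @param pulse_ms Pulse duration in ms (default 10).
#' @param ramp_ms Linear on/off ramp duration in ms (default 1).
#' @param rate_pps Pulse repetition rate in pulses per second (default 50).
#' @param total_s Total trill duration in seconds (default 2).
#' @return An object of class `pulse_train_spec`.
#' @export
pulse_train_spec <- function(carrier_hz = 5000, pulse_ms = 10, ramp_ms = 1,
                             rate_pps = 50, total_s = 2) {
  if (any(c(carrier_hz, pulse_ms, rate_pps, total_s) <= 0) || ramp_ms < 0)
    stop("pulse_train_spec: all parameters must be positive (ramp_ms >= 0)")
  if (pulse_ms > 1000 / rate_pps)
    stop("pulse_train_spec: pulse_ms exceeds the pulse period 1000/rate_pps")
  if (ramp_ms > pulse_ms / 2)
    stop("pulse_train_spec: ramp_ms exceeds pulse_ms/2")
  structure(list(carrier_hz = carrier_hz, pulse_ms = pulse_ms,
                 ramp_ms = ramp_ms, rate_pps = rate_pps, total_s = total_s),
            class = "pulse_train_spec")
}

#' Specification of a band-limited noise burst
#'
#' @param band_lo_hz Lower passband edge in Hz (default 2000).
#' @param band_hi_hz Upper passband edge in Hz (default 7000).
#' @param total_s Duration in seconds (default 4).
#' @param rng_seed Integer seed; identical seeds give identical (coherent)
#'   noise waveforms.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(band_lo_hz = 2000, band_hi_hz = 7000, total_s = 4,
                       rng_seed = 1L) {
  if (!(band_lo_hz > 0 && band_hi_hz > band_lo_hz))
    stop("noise_spec: need 0 < band_lo_hz < band_hi_hz")
  if (total_s <= 0) stop("noise_spec: total_s must be positive")
  if (is.null(rng_seed)) stop("noise_spec: rng_seed is required")
  structure(list(band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
                 total_s = total_s, rng_seed = as.integer(rng_seed)),
            class = "noise_spec")
}

#' A sound source within a scene
#'
#' Azimuth follows the behavioural convention: 0 is the frontal midline and
#' positive angles are to the animal's right.
#'
#' @param waveform A [pulse_train_spec()] or [noise_spec()].
#' @param azimuth_deg Signed azimuth in degrees, in [-180, 180].
#' @param level_db Broadcast level in dB re the package reference.
#' @param onset_s Broadcast onset in seconds; `NA` applies the default scene
#'   timing (masker 0.5 s, signal 1.5 s post-trigger).
#' @param coherent_group Optional label; noise sources sharing a label are
#'   rendered from the same waveform (coherent maskers).
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(waveform, azimuth_deg, level_db, onset_s = NA,
                        coherent_group = NULL) {
  if (!inherits(waveform, c("pulse_train_spec", "noise_spec")))
    stop("source_spec: waveform must be a pulse_train_spec or noise_spec")
  if (azimuth_deg < -180 || azimuth_deg > 180)
    stop("source_spec: azimuth_deg must lie in [-180, 180]")
  structure(list(waveform = waveform, azimuth_deg = azimuth_deg,
                 level_db = level_db, onset_s = onset_s,
                 coherent_group = coherent_group),
            class = "source_spec")
}

#' A timed multi-speaker acoustic scene
#'
#' @param sources List of [source_spec()] objects.
#' @param fs_hz Sample rate in Hz (default 44100, the DAQ rate).
#' @param record_s Acquisition duration in seconds (default 5: 0.5 s lead,
#'   4 s masker, 0.5 s tail).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(sources = list(), fs_hz = 44100, record_s = 5) {
  if (inherits(sources, "source_spec")) sources <- list(sources)
  stopifnot(fs_hz > 0, record_s > 0)
  ok <- vapply(sources, inherits, logical(1), what = "source_spec")
  if (!all(ok)) stop("scene_spec: sources must all be source_spec objects")
  structure(list(sources = sources, fs_hz = fs_hz, record_s = record_s),
            class = "scene_spec")
}

#' A sampled pressure trace
#'
#' @param samples Numeric amplitude series (dimensionless re reference).
#' @param fs_hz Sample rate in Hz.
#' @return An object of class `pressure_trace`.
#' @export
pressure_trace <- function(samples, fs_hz) {
  if (!all(is.finite(samples))) stop("pressure_trace: samples must be finite")
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("pressure_trace: %d samples at %g Hz (%.3f s), rms %.4g\n",
              length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz,
              rms(x$samples)))
  invisible(x)
}

trace_samples <- function(x) {
  if (inherits(x, "pressure_trace")) x$samples else as.numeric(x)
}

waveform_duration_s <- function(w) w$total_s

#' Synthesize a pulsed trill
#'
#' Tonal pulses at the carrier frequency with linear on/off ramps; samples
#' between pulses are exactly zero. The number of pulses is
#' `floor(total_s * rate_pps)`.
#'
#' @param spec A [pulse_train_spec()].
#' @param fs_hz Sample rate in Hz; must exceed twice the carrier.
#' @return A [pressure_trace()] of unit peak amplitude (before calibration).
#' @export
synth_pulse_train <- function(spec, fs_hz = 44100) {
  stopifnot(inherits(spec, "pulse_train_spec"))
  if (fs_hz <= 2 * spec$carrier_hz)
    stop("synth_pulse_train: fs_hz must exceed twice the carrier frequency")
  n <- round(spec$total_s * fs_hz)
  out <- numeric(n)
  npulse <- round(spec$pulse_ms / 1000 * fs_hz)
  nramp <- round(spec$ramp_ms / 1000 * fs_hz)
  t <- (seq_len(npulse) - 1) / fs_hz
  tone <- sin(2 * pi * spec$carrier_hz * t)
  env <- rep(1, npulse)
  if (nramp > 0) {
    env[seq_len(nramp)] <- seq_len(nramp) / nramp
    env[npulse - nramp + seq_len(nramp)] <- rev(seq_len(nramp) / nramp)
  }
  pulse <- tone * env
  k <- floor(spec$total_s * spec$rate_pps)
  for (i in seq_len(k)) {
    start <- round((i - 1) / spec$rate_pps * fs_hz)
    idx <- start + seq_len(npulse)
    idx <- idx[idx <= n]
    out[idx] <- out[idx] + pulse[seq_along(idx)]
  }
  pressure_trace(out, fs_hz)
}

#' Synthesize band-limited Gaussian noise
#'
#' White Gaussian noise is shaped in the frequency domain: bins outside the
#' passband are zeroed, with raised-cosine tapers just inside the band edges.
#' Out-of-band power is therefore far more than 40 dB below in-band power.
#' The result is deterministic given `spec$rng_seed`, which is how coherent
#' (identical-waveform) maskers are produced.
#'
#' @param spec A [noise_spec()].
#' @param fs_hz Sample rate in Hz; the upper band edge must be below Nyquist.
#' @param transition_hz Width of the raised-cosine tapers, placed inside the
#'   passband (default: 200 Hz or a tenth of the bandwidth, whichever is
#'   smaller).
#' @return A [pressure_trace()] with unit long-term RMS (before calibration).
#' @export
synth_noise <- function(spec, fs_hz = 44100, transition_hz = NULL) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$band_hi_hz >= fs_hz / 2)
    stop("synth_noise: band_hi_hz must be below Nyquist (fs_hz/2)")
  if (is.null(transition_hz))
    transition_hz <- min(200, (spec$band_hi_hz - spec$band_lo_hz) / 10)
  n <- round(spec$total_s * fs_hz)
  x <- with_seed(spec$rng_seed, stats::rnorm(n))
  xf <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs_hz / n
  f <- pmin(f, fs_hz - f)  # fold to physical frequency
  w <- numeric(n)
  lo <- spec$band_lo_hz
  hi <- spec$band_hi_hz
  tw <- transition_hz
  inband <- f >= lo & f <= hi
  w[inband] <- 1
  ramp_up <- f >= lo & f < lo + tw
  w[ramp_up] <- 0.5 * (1 - cos(pi * (f[ramp_up] - lo) / tw))
  ramp_dn <- f > hi - tw & f <= hi
  w[ramp_dn] <- 0.5 * (1 - cos(pi * (hi - f[ramp_dn]) / tw))
  y <- Re(stats::fft(xf * w, inverse = TRUE)) / n
  y <- y / rms(y)
  pressure_trace(y, fs_hz)
}

#' Calibrate a trace to a target level
#'
#' Two conventions mirror the calibration of signals and maskers: target
#' signals are calibrated as peak RMS (the maximum of a short sliding-RMS
#' window, which sits on pulse interiors), maskers as long-term RMS over the
#' whole trace. dB arithmetic is 20*log10 on amplitude.
#'
#' @param trace A [pressure_trace()].
#' @param level_db Target level in dB re the package reference.
#' @param mode `"peak_rms"` or `"longterm_rms"`.
#' @param window_ms Sliding-RMS window for `peak_rms` mode (default 5 ms,
#'   well inside a 10 ms pulse).
#' @return The rescaled [pressure_trace()].
#' @export
set_level <- function(trace, level_db, mode = c("peak_rms", "longterm_rms"),
                      window_ms = 5) {
  stopifnot(inherits(trace, "pressure_trace"))
  mode <- match.arg(mode)
  x <- trace$samples
  if (all(x == 0)) stop("set_level: all-zero trace has undefined scaling")
  cur <- if (mode == "peak_rms") {
    w <- max(2, round(window_ms / 1000 * trace$fs_hz))
    max(sliding_rms(x, w))
  } else {
    rms(x)
  }
  pressure_trace(x * db_to_amp(level_db) / cur, trace$fs_hz)
}

#' Assemble a scene into per-source aligned traces
#'
#' Each source's waveform is synthesized, calibrated (pulse trains as peak
#' RMS, noise as long-term RMS), and zero-padded into the acquisition window
#' at its onset. Default timing places the masker 0.5 s and the signal 1.5 s
#' post-trigger, embedding a 2 s signal symmetrically in a 4 s masker.
#' Noise sources sharing a `coherent_group` label are rendered from the first
#' member's waveform spec, so their waveforms are identical.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `scene_render`: per-source traces (list of
#'   numeric vectors of equal length), onsets, azimuths, levels and the
#'   sample rate.
#' @export
assemble_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- round(spec$record_s * spec$fs_hz)
  srcs <- spec$sources
  k <- length(srcs)
  # coherent groups share the first member's waveform spec
  wf_specs <- lapply(srcs, `[[`, "waveform")
  groups <- vapply(srcs, function(s)
    if (is.null(s$coherent_group)) NA_character_ else as.character(s$coherent_group),
    character(1))
  for (g in unique(groups[!is.na(groups)])) {
    members <- which(!is.na(groups) & groups == g)
    for (m in members[-1]) wf_specs[[m]] <- wf_specs[[members[1]]]
  }
  # synthesize each distinct waveform once
  keys <- vapply(wf_specs, function(w) paste(class(w)[1],
                                             paste(unlist(w), collapse = ","),
                                             sep = ":"), character(1))
  cache <- list()
  traces <- vector("list", k)
  onsets <- numeric(k)
  azimuths <- numeric(k)
  levels <- numeric(k)
  for (i in seq_len(k)) {
    s <- srcs[[i]]
    w <- wf_specs[[i]]
    onset <- s$onset_s
    if (is.na(onset)) onset <- if (inherits(w, "noise_spec")) 0.5 else 1.5
    if (onset < 0 || onset + waveform_duration_s(w) > spec$record_s + 1e-9)
      stop("assemble_scene: source does not fit within record_s")
    if (is.null(cache[[keys[i]]])) {
      cache[[keys[i]]] <- if (inherits(w, "noise_spec"))
        synth_noise(w, spec$fs_hz) else synth_pulse_train(w, spec$fs_hz)
    }
    mode <- if (inherits(w, "noise_spec")) "longterm_rms" else "peak_rms"
    wave <- set_level(cache[[keys[i]]], s$level_db, mode = mode)$samples
    full <- numeric(n)
    start <- round(onset * spec$fs_hz)
    idx <- start + seq_along(wave)
    idx_ok <- idx <= n
    full[idx[idx_ok]] <- wave[idx_ok]
    traces[[i]] <- full
    onsets[i] <- onset
    azimuths[i] <- s$azimuth_deg
    levels[i] <- s$level_db
  }
  structure(list(spec = spec, traces = traces, onsets_s = onsets,
                 azimuths_deg = azimuths, levels_db = levels,
                 fs_hz = spec$fs_hz, n = n),
            class = "scene_render")
}

#' @export
print.scene_render <- function(x, ...) {
  cat(sprintf("scene_render: %d source(s), %.3f s at %g Hz\n",
              length(x$traces), x$n / x$fs_hz, x$fs_hz))
  for (i in seq_along(x$traces))
    cat(sprintf("  source %d: azimuth %+.1f deg, %.1f dB, onset %.2f s\n",
                i, x$azimuths_deg[i], x$levels_db[i], x$onsets_s[i]))
  invisible(x)
}

#' Mix a rendered scene to a single pressure trace
#'
#' @param scene A `scene_render` from [assemble_scene()].
#' @return A [pressure_trace()] containing the sample-wise sum of sources.
#' @export
scene_mix <- function(scene) {
  stopifnot(inherits(scene, "scene_render"))
  pressure_trace(Reduce(`+`, scene$traces, numeric(scene$n)), scene$fs_hz)
}
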