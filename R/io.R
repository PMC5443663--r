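# Trace and configuration I/O: delimited-text traces (the primary exchange
# format), a minimal PCM16 WAV export, and YAML scene configurations.

#' Write a pressure trace as 2-column delimited text (time_s, amplitude)
#'
#' @param trace A [pressure_trace()].
#' @param path Output path.
#' @export
write_trace_txt <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  utils::write.table(
    data.frame(time_s = (seq_along(trace$samples) - 1) / trace$fs_hz,
               amplitude = trace$samples),
    path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Read a pressure trace from 2-column delimited text
#'
#' @param path Input path (columns time_s, amplitude; header optional).
#' @return A [pressure_trace()]; the sample rate is recovered from the
#'   median time step.
#' @export
read_trace_txt <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#")
  fs <- 1 / stats::median(diff(d[[1]]))
  pressure_trace(d[[2]], round(fs))
}

#' Write traces as a PCM16 WAV file
#'
#' Minimal RIFF/WAVE writer (16-bit integer PCM, mono or stereo). Samples
#' are scaled by `scale`; the default maps the largest absolute sample to
#' 99% full scale.
#'
#' @param traces A [pressure_trace()] (mono) or a list of two for stereo
#'   (e.g. the `left`/`right` of `tympanal_traces`).
#' @param path Output path.
#' @param scale Amplitude scale factor, or `NULL` for automatic.
#' @export
write_wav <- function(traces, path, scale = NULL) {
  if (inherits(traces, "pressure_trace")) traces <- list(traces)
  if (inherits(traces, "tympanal_traces"))
    traces <- list(pressure_trace(traces$left, traces$fs_hz),
                   pressure_trace(traces$right, traces$fs_hz))
  fs <- traces[[1]]$fs_hz
  ch <- lapply(traces, trace_samples)
  nch <- length(ch)
  n <- length(ch[[1]])
  if (is.null(scale)) scale <- 0.99 / max(abs(unlist(ch)), 1e-300)
  inter <- matrix(unlist(ch), ncol = nch)
  pcm <- as.integer(pmax(pmin(round(t(inter) * scale * 32767), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(round(fs)), con, size = 4, endian = "little")
  writeBin(as.integer(round(fs) * nch * 2L), con, size = 4, endian = "little")
  writeBin(nch * 2L, con, size = 2, endian = "little")      # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Export a spike train as delimited text (one event time per line)
#'
#' @param spikes A [spike_train()].
#' @param path Output path.
#' @export
write_spike_train <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train"))
  utils::write.table(data.frame(time_s = spikes$times_s),
                     path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

spec_to_list <- function(s) {
  out <- unclass(s)
  if (!is.null(out$waveform)) {
    out$waveform_type <- class(s$waveform)[1]
    out$waveform <- unclass(s$waveform)
  }
  out
}

#' Write a scene specification to a YAML configuration file
#'
#' @param spec A [scene_spec()].
#' @param path Output path.
#' @export
write_scene_config <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  cfg <- list(fs_hz = spec$fs_hz, record_s = spec$record_s,
              sources = lapply(spec$sources, spec_to_list))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a scene specification from a YAML configuration file
#'
#' @param path Path to a file written by [write_scene_config()] (or edited
#'   by hand; see that function for the schema).
#' @return A [scene_spec()].
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sources <- lapply(cfg$sources, function(s) {
    w <- s$waveform
    wf <- if (identical(s$waveform_type, "noise_spec")) {
      noise_spec(w$band_lo_hz, w$band_hi_hz, w$total_s, w$rng_seed)
    } else {
      pulse_train_spec(w$carrier_hz, w$pulse_ms, w$ramp_ms, w$rate_pps,
                       w$total_s)
    }
    source_spec(wf, s$azimuth_deg, s$level_db,
                onset_s = if (is.null(s$onset_s)) NA else s$onset_s,
                coherent_group = s$coherent_group)
  })
  scene_spec(sources, fs_hz = cfg$fs_hz, record_s = cfg$record_s)
}
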