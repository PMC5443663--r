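# Stimulus synthesis: trill structure, band-limited noise, calibration,
# and scene assembly.

count_pulses_by_envelope <- function(trace, thresh = 0.3) {
  env <- sliding_rms(trace$samples, max(2, round(trace$fs_hz / 1000)))
  above <- env > thresh * max(env)
  sum(diff(c(FALSE, above)) == 1)
}

test_that("trill structure is recoverable by envelope analysis", {
  tr <- synth_pulse_train(pulse_train_spec(), 44100)
  expect_length(tr$samples, 88200)
  expect_equal(count_pulses_by_envelope(tr), 100)
  # inter-pulse samples exactly zero, 50% duty cycle
  expect_equal(mean(tr$samples == 0) > 0.45 && mean(tr$samples == 0) < 0.55,
               TRUE)
  # 2-pulse stimulus: 40 ms at 50 pps
  two <- synth_pulse_train(pulse_train_spec(total_s = 0.04), 44100)
  expect_equal(count_pulses_by_envelope(two), 2)
  # unramped single pulse: interior RMS is 1/sqrt(2) of peak amplitude
  one <- synth_pulse_train(pulse_train_spec(ramp_ms = 0, total_s = 0.02),
                           44100)
  interior <- one$samples[1:441]  # the 10 ms pulse (50 carrier periods)
  expect_equal(rms(interior), 1 / sqrt(2), tolerance = 1e-6)
})

test_that("pulse train spec rejects invalid timing", {
  expect_error(pulse_train_spec(pulse_ms = 25, rate_pps = 50), "period")
  expect_error(pulse_train_spec(ramp_ms = 6, pulse_ms = 10), "ramp")
  expect_error(synth_pulse_train(pulse_train_spec(), fs_hz = 8000), "carrier")
})

test_that("band-limited noise is deterministic and band-limited", {
  a <- synth_noise(noise_spec(rng_seed = 42), 44100)
  b <- synth_noise(noise_spec(rng_seed = 42), 44100)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples,
                         synth_noise(noise_spec(rng_seed = 43), 44100)$samples))
  expect_error(synth_noise(noise_spec(band_hi_hz = 30000), 44100), "Nyquist")
  # >= 40 dB in-band/out-of-band rejection, property over 20 seeds
  for (s in 1:20) {
    nz <- synth_noise(noise_spec(total_s = 0.5, rng_seed = s), 44100)
    ps <- Mod(stats::fft(nz$samples))^2
    f <- (seq_along(ps) - 1) * 44100 / length(ps)
    f <- pmin(f, 44100 - f)
    inband <- f >= 2000 & f <= 7000
    out <- !inband & f > 100   # exclude DC leakage region
    rejection_db <- 10 * log10(mean(ps[inband]) / max(mean(ps[out]), 1e-300))
    expect_gt(rejection_db, 40)
    # passband covers the 5 kHz carrier it must mask
    near5k <- f > 4800 & f < 5200
    expect_gt(mean(ps[near5k]), 0.5 * mean(ps[inband]))
  }
})

test_that("set_level implements dB arithmetic and is idempotent", {
  tr <- synth_pulse_train(pulse_train_spec(total_s = 0.1), 44100)
  a <- set_level(tr, 70)
  b <- set_level(tr, 76.0205999)
  expect_equal(max(abs(b$samples)) / max(abs(a$samples)), 2, tolerance = 1e-3)
  # idempotent
  a2 <- set_level(a, 70)
  expect_equal(a2$samples, a$samples, tolerance = 1e-9)
  # long-term RMS mode calibrates whole-trace RMS
  nz <- set_level(synth_noise(noise_spec(total_s = 0.3, rng_seed = 1), 44100),
                  76, mode = "longterm_rms")
  expect_equal(amp_to_db(rms(nz$samples)), 76, tolerance = 1e-9)
  expect_error(set_level(pressure_trace(numeric(100), 44100), 70), "zero")
})

test_that("two coherent maskers summed in phase gain 6.02 dB", {
  nz <- set_level(synth_noise(noise_spec(total_s = 0.3, rng_seed = 9), 44100),
                  70, mode = "longterm_rms")
  combined <- amp_to_db(rms(nz$samples + nz$samples))
  expect_equal(combined, 76.02, tolerance = 0.005)
})

test_that("scene assembly applies the default embedded timing", {
  spec <- scene_spec(list(
    source_spec(pulse_train_spec(), 0, 76),
    source_spec(noise_spec(rng_seed = 1), 90, 76)))
  sc <- assemble_scene(spec)
  expect_equal(sc$onsets_s, c(1.5, 0.5))
  # signal starts 1.0 s after masker onset and ends 1.0 s before masker end
  sig <- sc$traces[[1]]
  msk <- sc$traces[[2]]
  fs <- sc$fs_hz
  sig_span <- range(which(sig != 0)) / fs
  msk_span <- range(which(msk != 0)) / fs
  expect_equal(sig_span[1] - msk_span[1], 1, tolerance = 1e-3)
  # the trill is 50% duty cycle, so its last nonzero sample precedes the
  # scheduled signal offset by half a pulse period
  expect_equal(msk_span[2] - sig_span[2], 1.01, tolerance = 1e-2)
})

test_that("scene assembly handles empty scenes, coherence, and errors", {
  empty <- assemble_scene(scene_spec(list(), record_s = 2))
  expect_equal(scene_mix(empty)$samples, numeric(2 * 44100))
  # coherent group: identical waveforms at different azimuths
  spec <- scene_spec(list(
    source_spec(noise_spec(rng_seed = 5), -90, 70, coherent_group = "m"),
    source_spec(noise_spec(rng_seed = 99), 90, 70, coherent_group = "m")))
  sc <- assemble_scene(spec)
  on <- round(0.5 * sc$fs_hz)
  expect_identical(sc$traces[[1]][on + 1:1000], sc$traces[[2]][on + 1:1000])
  # onset beyond the record is a parameter error
  expect_error(assemble_scene(scene_spec(list(
    source_spec(pulse_train_spec(), 0, 70, onset_s = 4.5)), record_s = 5)),
    "fit")
})

test_that("scene configs and traces round-trip through files", {
  spec <- scene_spec(list(
    source_spec(pulse_train_spec(), 0, 76),
    source_spec(noise_spec(rng_seed = 3), 90, 70, coherent_group = "m")),
    record_s = 5)
  f <- tempfile(fileext = ".yaml")
  write_scene_config(spec, f)
  spec2 <- read_scene_config(f)
  expect_equal(assemble_scene(spec2)$traces, assemble_scene(spec)$traces)
  tr <- synth_pulse_train(pulse_train_spec(total_s = 0.05), 44100)
  ftxt <- tempfile(fileext = ".txt")
  write_trace_txt(tr, ftxt)
  tr2 <- read_trace_txt(ftxt)
  expect_equal(tr2$fs_hz, 44100)
  expect_equal(tr2$samples, tr$samples, tolerance = 1e-6)
  fwav <- tempfile(fileext = ".wav")
  write_wav(tr, fwav)
  hdr <- readBin(fwav, "raw", 44)
  expect_identical(rawToChar(hdr[1:4]), "RIFF")
  expect_identical(rawToChar(hdr[9:16]), "WAVEfmt ")
})

test_that("geometry utilities give the physical scale of the system", {
  expect_equal(best_itd_us(500e-6), 1.45, tolerance = 0.01)
  expect_equal(wavelength_cm(5000), 6.89, tolerance = 0.01)
})
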