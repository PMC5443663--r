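# Generative ear model: directionality curve, per-ear rendering, phasic
# afferents, and heading simulation.

test_that("directionality curve is antisymmetric, monotone, bounded", {
  cv <- default_curve()
  expect_equal(ivad_at(cv, 0), 0)
  th <- seq(-180, 180, by = 5)
  expect_equal(ivad_at(cv, -th), -ivad_at(cv, th))
  expect_true(all(diff(ivad_at(cv, th)) > 0))
  expect_true(all(abs(ivad_at(cv, th)) <= 10))
  # analytic inverse round-trips
  expect_equal(azimuth_at(cv, ivad_at(cv, c(-77, -10, 0, 33, 88))),
               c(-77, -10, 0, 33, 88), tolerance = 1e-10)
  # IVAD at 90 deg with max 10 dB, slope 30 deg (direct evaluation of the
  # sigmoid: 10 * (2/(1 + exp(-3)) - 1))
  expect_equal(ivad_at(cv, 90), 9.0515, tolerance = 1e-4)
})

test_that("tabulated directionality interpolates and inverts", {
  az <- seq(-90, 90, by = 30)
  tab <- directionality_table(az, ivad_at(default_curve(), az))
  expect_equal(ivad_at(tab, az), ivad_at(default_curve(), az))
  expect_equal(azimuth_at(tab, ivad_at(tab, 60)), 60, tolerance = 1e-9)
  f <- tempfile(fileext = ".tsv")
  writeLines(c("azimuth_deg\tivad_db",
               paste(az, round(ivad_at(default_curve(), az), 4), sep = "\t")),
             f)
  tab2 <- read_directionality_table(f)
  expect_equal(tab2$azimuth_deg, az)
})

test_that("rendering is symmetric at the midline and splits IVAD at 90", {
  sc <- single_source_scene(0)
  noiseless <- ear_gain_model(default_curve(), meas_noise_db = NULL)
  ty <- render_tympanal(sc, noiseless)
  expect_identical(ty$left, ty$right)
  # lateral source: interaural RMS ratio equals IVAD(theta) within 0.2 dB
  # when measurement noise sits 40 dB below the source
  sc90 <- single_source_scene(90, level_db = 70)
  ty90 <- render_tympanal(sc90, ear_gain_model(default_curve(), 30), seed = 1)
  act <- round(1.5 * 44100):round(3.5 * 44100)
  ratio_db <- 20 * log10(rms(ty90$right[act]) / rms(ty90$left[act]))
  expect_equal(ratio_db, 9.0515, tolerance = 0.2)
})

test_that("a lateral masker raises the ipsilateral floor only", {
  # frontal signal + right masker: masker-driven floor higher in the right
  # ear, signal-driven increment equal in both
  spec <- scene_spec(list(
    source_spec(pulse_train_spec(), 0, 76),
    source_spec(noise_spec(rng_seed = 7), 90, 76)))
  ty <- render_tympanal(assemble_scene(spec),
                        ear_gain_model(default_curve(), meas_noise_db = NULL))
  floor_idx <- round(0.6 * 44100):round(1.4 * 44100)
  expect_gt(rms(ty$right[floor_idx]), rms(ty$left[floor_idx]))
  w <- trill_windows(1.5, 2)
  ea_r <- effective_amplitude(ty$right, 44100, w$signal, w$masker)
  ea_l <- effective_amplitude(ty$left, 44100, w$signal, w$masker)
  expect_gt(ea_l$value_db, ea_r$value_db)  # contra ear keeps the advantage
})

test_that("coherent symmetric maskers cancel the effective IVAD", {
  model <- ear_gain_model(default_curve(), 30)
  ivads <- vapply(1:20, function(s) {
    spec <- scene_spec(list(
      source_spec(pulse_train_spec(), 0, 76),
      source_spec(noise_spec(rng_seed = s), -90, 70, coherent_group = "m"),
      source_spec(noise_spec(rng_seed = s), 90, 70, coherent_group = "m")))
    ivad_of_scene(assemble_scene(spec), model, seed = 1000 + s)
  }, numeric(1))
  expect_lt(abs(mean(ivads)), 0.3)
})

test_that("phasic afferents mark pulse onsets and respect refractoriness", {
  trl <- set_level(synth_pulse_train(pulse_train_spec(), 44100), 70)
  pad <- pressure_trace(c(numeric(22050), trl$samples), 44100)
  sp <- spikes_from_trace(pad, quiet_s = c(0, 0.4),
                          spec = afferent_spec("I", jitter_ms = 0))
  expect_length(sp$times_s, 100)   # one spike per pulse in a 2 s trill
  # Type II: several onset spikes per pulse
  sp2 <- spikes_from_trace(pad, quiet_s = c(0, 0.4),
                           spec = afferent_spec("II", jitter_ms = 0))
  expect_gt(length(sp2$times_s), 150)
  # all-zero trace: no spikes
  z <- pressure_trace(numeric(44100), 44100)
  expect_length(spikes_from_trace(z, quiet_s = c(0, 0.5))$times_s, 0)
  # refractoriness holds for every seed, including under jitter and noise
  for (s in 1:10) {
    spec <- scene_spec(list(source_spec(noise_spec(total_s = 0.8, rng_seed = s),
                                        20, 72, onset_s = 0.3)), record_s = 1.2)
    ty <- render_tympanal(assemble_scene(spec),
                          ear_gain_model(default_curve(), 40), seed = s)
    spn <- spikes_from_trace(ty$left, 44100, quiet_s = c(0, 0.25),
                             spec = afferent_spec("I", jitter_ms = 0.3),
                             seed = s)
    if (length(spn$times_s) > 1)
      expect_true(all(diff(spn$times_s) >= 0.004 - 1e-12))
  }
})

test_that("crossings inside the dead time are suppressed", {
  fs <- 44100
  x <- numeric(round(0.5 * fs))
  tone <- sin(2 * pi * 5000 * seq(0, 0.001, by = 1 / fs))
  # two burst onsets 2 ms apart; refractory period is 4 ms
  i1 <- round(0.3 * fs)
  i2 <- round(0.302 * fs)
  x[i1 + seq_along(tone)] <- tone
  x[i2 + seq_along(tone)] <- tone
  sp <- spikes_from_trace(x, fs, quiet_s = c(0, 0.2),
                          spec = afferent_spec("I", jitter_ms = 0))
  expect_length(sp$times_s, 1)
})

test_that("simulate_heading is antisymmetric and sign-consistent", {
  cv <- default_curve()
  expect_equal(simulate_heading(0, cv), 0)
  expect_equal(simulate_heading(3, cv), -simulate_heading(-3, cv))
  expect_equal(sign(simulate_heading(c(-4, 2), cv)), c(-1, 1))
  expect_equal(simulate_heading(2, gain_deg_per_db = 5), 10)
  # beyond the curve range: clamped with a warning
  expect_warning(h <- simulate_heading(15, cv), "clamp")
  expect_equal(h, 180)
})

test_that("generate -> analyze -> invert recovers the source azimuth", {
  model <- ear_gain_model(default_curve(), 30)
  for (th in c(-45, 0, 45)) {
    sc <- single_source_scene(th)
    for (s in 1:5) {
      ivad <- ivad_of_scene(sc, model, seed = 100 * s + th)
      expect_lt(abs(azimuth_at(default_curve(), ivad) - th), 3)
    }
  }
})
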