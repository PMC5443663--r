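# Vibrometry analysis: sliding RMS, effective amplitude, IVAD, sigmoid
# fitting and inversion to a predicted direction.

test_that("sliding RMS matches brute-force recomputation", {
  set.seed(31)
  x <- rnorm(5000)
  w <- 127
  out <- sliding_rms(x, w)
  h_lo <- floor((w - 1) / 2)
  h_hi <- w - 1 - h_lo
  for (i in sample(seq_along(x), 10)) {
    idx <- max(1, i - h_lo):min(length(x), i + h_hi)
    expect_equal(out[i], sqrt(mean(x[idx]^2)), tolerance = 1e-12)
  }
  # constant input maps to |c| everywhere (shrink-to-valid edges)
  expect_equal(sliding_rms(rep(-3, 100), 10), rep(3, 100))
  # unit sinusoid, window an integer number of periods: 1/sqrt(2) interior
  # (48 kHz and 1 kHz give an exact 48-sample period)
  fs <- 48000
  sine <- sin(2 * pi * 1000 * (0:(fs / 10)) / fs)
  w2 <- fs / 1000 * 4  # 4 periods
  sm <- sliding_rms(sine, w2)
  interior <- sm[(w2 + 1):(length(sm) - w2)]
  expect_equal(max(abs(interior - 1 / sqrt(2))), 0, tolerance = 1e-9)
  expect_error(sliding_rms(1:10, 11), "window")
})

test_that("effective amplitude is the windowed dB difference", {
  fs <- 1000
  x <- c(rep(1, 500), rep(2, 500))   # masker epoch RMS 1, signal epoch RMS 2
  ea <- effective_amplitude(x, fs, signal_windows = c(0.6, 0.9),
                            masker_windows = c(0.1, 0.4))
  expect_equal(ea$value_db, 20 * log10(2), tolerance = 1e-9)
  # equal windows: 0 dB; per-iteration values pair up
  ea0 <- effective_amplitude(x, fs,
                             signal_windows = rbind(c(0.1, 0.2), c(0.6, 0.7)),
                             masker_windows = rbind(c(0.3, 0.4), c(0.75, 0.85)))
  expect_equal(ea0$per_iteration_db, c(0, 0))
  expect_error(effective_amplitude(c(rep(1, 500), rep(0, 500)), fs,
                                   signal_windows = c(0.1, 0.2),
                                   masker_windows = c(0.7, 0.8)),
               "zero")
})

test_that("pulse-protocol windows follow the 30 ms / 200 ms scheme", {
  w <- pulse_protocol_windows(c(1, 1.4))
  expect_equal(w$signal[1, ], c(1, 1.03))
  expect_equal(w$masker[1, ], c(1.2, 1.23))
  expect_equal(w$signal[2, 1], 1.4)
})

test_that("IVAD is the contra minus ipsi difference", {
  expect_equal(compute_ivad(5, 2)$value_db, 3)
  expect_equal(compute_ivad(2, 2)$value_db, 0)
  e1 <- structure(list(value_db = 4.5), class = "effective_amplitude")
  e2 <- structure(list(value_db = 1.25), class = "effective_amplitude")
  expect_equal(compute_ivad(e1, e2, snr_db = 0)$value_db, 3.25)
})

test_that("sigmoid fitting recovers exact and noisy logistics", {
  xs <- seq(-90, 90, by = 10)
  true_par <- c(y0 = -9, a = 18, x0 = 4, b = 15)
  ys <- true_par[1] + true_par[2] / (1 + exp(-(xs - true_par[3]) / true_par[4]))
  fit <- fit_sigmoid(xs, ys)
  expect_true(fit$converged)
  expect_equal(unname(fit$par), unname(true_par), tolerance = 1e-4)
  # degenerate constant data: flagged, no exception
  flat <- fit_sigmoid(xs, rep(2, length(xs)))
  expect_false(flat$converged)
  # noisy logistic: sigma = 5% of range, n = 20; median recovery over 50
  # seeds within 10% on each parameter
  errs <- sapply(1:50, function(s) {
    set.seed(s)
    x20 <- seq(-90, 90, length.out = 20)
    yn <- true_par[1] + true_par[2] / (1 + exp(-(x20 - true_par[3]) / true_par[4])) +
      rnorm(20, sd = 0.05 * 18)
    f <- fit_sigmoid(x20, yn)
    abs(f$par - true_par) / c(18, 18, 180, 15)  # relative to natural scales
  })
  expect_true(all(apply(errs, 1, median) < 0.10))
})

test_that("direction prediction inverts the fitted curve exactly", {
  xs <- seq(-90, 90, by = 10)
  ys <- ivad_at(default_curve(), xs)
  fit <- fit_sigmoid(xs, ys)
  # inversion is the identity on the curve interior
  for (x0 in c(-80, -33, 0, 12, 61))
    expect_equal(predict_direction(predict(fit, x0), fit), x0,
                 tolerance = 1e-6)
  # antisymmetric data: fitted curve passes within 0.1 dB of 0 at x = 0
  expect_lt(abs(predict(fit, 0)), 0.1)
  # out-of-range IVAD clamps with a warning
  expect_warning(p <- predict_direction(99, fit), "clamp")
  expect_equal(p, 90)
  expect_error(predict_direction(0, fit_sigmoid(xs, rep(1, length(xs)))),
               "converge")
})

test_that("effective amplitude rises with SNR and favours the contra ear", {
  model <- ear_gain_model(default_curve(), 30)
  mean_ea <- function(snr) {
    spec <- scene_spec(list(
      source_spec(pulse_train_spec(), 0, 76 + snr),
      source_spec(noise_spec(rng_seed = 11), 90, 76)))
    ty <- render_tympanal(assemble_scene(spec), model, seed = 5)
    w <- trill_windows(1.5, 2)
    effective_amplitude(ty$left, 44100, w$signal, w$masker)$value_db
  }
  eas <- vapply(c(-6, 0, 6), mean_ea, numeric(1))
  expect_true(all(diff(eas) > 0))
  # contralateral dominance for a lateral masker in >= 95% of seeds
  for (sep in c(6, 90)) {
    wins <- vapply(1:20, function(s) {
      spec <- scene_spec(list(
        source_spec(pulse_train_spec(), 0, 76),
        source_spec(noise_spec(rng_seed = s), sep, 76)))
      ivad_of_scene(assemble_scene(spec), model, seed = 300 + s) < 0
    }, logical(1))
    expect_gte(mean(wins), 0.95)
  }
})
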