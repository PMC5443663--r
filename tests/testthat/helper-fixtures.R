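# Shared in-code fixtures for the test suite.

default_curve <- function() directionality_curve(max_ivad_db = 10,
                                                 slope_deg = 30)

# A short single-source scene for the recovery chain: one 2 s trill at a
# given azimuth, signal onset 1.5 s, 3.5 s acquisition (so the noise-floor
# epoch is the second before signal onset).
single_source_scene <- function(azimuth_deg, level_db = 70, fs_hz = 44100) {
  assemble_scene(scene_spec(
    list(source_spec(pulse_train_spec(), azimuth_deg, level_db,
                     onset_s = 1.5)),
    fs_hz = fs_hz, record_s = 3.5))
}

# Effective interaural amplitude difference (right minus left) of a
# rendered scene using the trill window schedule.
ivad_of_scene <- function(scene, model, seed) {
  ty <- render_tympanal(scene, model, seed = seed)
  w <- trill_windows(1.5, 2)
  ea_r <- effective_amplitude(ty$right, ty$fs_hz, w$signal, w$masker)
  ea_l <- effective_amplitude(ty$left, ty$fs_hz, w$signal, w$masker)
  ea_r$value_db - ea_l$value_db
}

# Uniform angles in degrees.
runif_deg <- function(n) stats::runif(n, 0, 360)

# Wrapped normal sample (degrees) around a mean direction.
rnorm_deg <- function(n, mean_deg = 0, sd_deg = 20) {
  ormiasrm::wrap_deg(stats::rnorm(n, mean_deg, sd_deg))
}
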