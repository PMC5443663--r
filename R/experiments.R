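# In-silico replicas of the behavioural and physiological experiments,
# wiring scene synthesis -> ear model -> analyses -> statistics. All
# randomness descends from a single configuration seed, so a run is
# deterministic and its manifest byte-reproducible.

#' Experiment configuration
#'
#' Defaults mirror the study design: 13 flies, target signal at 76 dB,
#' masker at 76 dB, 6 and 90 degree separations, SNRs of -6/0/+6 dB for
#' behaviour and -18..+6 dB in 6 dB steps for the nerve protocol.
#'
#' @param experiment One of `"exp1_thresholds"`, `"exp2_snr_separation"`,
#'   `"exp3_symmetry"`, `"ldv"`, `"nerve"`.
#' @param n_flies Number of simulated animals (default 13; the nerve
#'   protocol uses `n_units`).
#' @param reps Responses per condition per fly (default 3 for the SNR
#'   experiment, 5 for the symmetry experiment).
#' @param separations Signal-masker separations in degrees.
#' @param snrs Broadcast SNRs in dB.
#' @param signal_db Target-signal level (peak RMS) in dB.
#' @param masker_db Masker level (long-term RMS) in dB.
#' @param curve Tympanal [directionality_curve()].
#' @param meas_noise_db Measurement-noise floor (dB).
#' @param motor_noise_deg Per-trial SD of heading motor noise (default 5).
#' @param criterion_db Mean behavioural response criterion on the best-ear
#'   effective amplitude (dB above the noise floor, default 1.5).
#' @param n_units Simulated nerve preparations (default 10).
#' @param sweeps Sweeps per level in the nerve protocol (default 20).
#' @param fs_hz Sample rate (default 44100).
#' @param seed Master seed (default 1).
#' @param out_dir Optional output directory for tables/manifest/figures.
#' @param make_figures Write simple summary figures when `out_dir` is set.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("exp1_thresholds",
                                             "exp2_snr_separation",
                                             "exp3_symmetry", "ldv", "nerve"),
                              n_flies = 13, reps = NULL,
                              separations = c(6, 90), snrs = c(-6, 0, 6),
                              signal_db = 76, masker_db = 76,
                              curve = directionality_curve(),
                              meas_noise_db = 30, motor_noise_deg = 5,
                              criterion_db = 1.5, n_units = 10, sweeps = 20,
                              fs_hz = 44100, seed = 1, out_dir = NULL,
                              make_figures = FALSE) {
  experiment <- match.arg(experiment)
  if (is.null(reps))
    reps <- switch(experiment, exp2_snr_separation = 3, exp3_symmetry = 5, 3)
  structure(list(experiment = experiment, n_flies = n_flies, reps = reps,
                 separations = separations, snrs = snrs,
                 signal_db = signal_db, masker_db = masker_db, curve = curve,
                 meas_noise_db = meas_noise_db,
                 motor_noise_deg = motor_noise_deg,
                 criterion_db = criterion_db, n_units = n_units,
                 sweeps = sweeps, fs_hz = fs_hz, seed = seed,
                 out_dir = out_dir, make_figures = make_figures),
            class = "experiment_config")
}

# A behavioural scene: 2 s trill at 0 deg (onset 1.5 s) embedded in 4 s
# masker(s) (onset 0.5 s) within a 5 s acquisition.
behaviour_scene <- function(signal_db, masker_db = NULL, masker_az = numeric(0),
                            coherent = FALSE, fs_hz = 44100, noise_seed = 1,
                            signal_total_s = 2) {
  sources <- list(source_spec(pulse_train_spec(total_s = signal_total_s),
                              azimuth_deg = 0, level_db = signal_db))
  if (length(masker_az)) {
    grp <- if (coherent) "m" else NULL
    for (i in seq_along(masker_az)) {
      seed_i <- if (coherent) noise_seed else child_seed(noise_seed, i)
      sources <- c(sources, list(source_spec(
        noise_spec(rng_seed = seed_i), azimuth_deg = masker_az[i],
        level_db = masker_db, coherent_group = grp)))
    }
  }
  assemble_scene(scene_spec(sources, fs_hz = fs_hz, record_s = 5))
}

# Effective amplitudes of both ears for a behavioural scene (trill epoch vs
# the masker-alone second before signal onset) and the signed interaural
# difference (right minus left).
measure_trial_ivad <- function(scene, model, seed = NULL,
                               signal_onset_s = 1.5, signal_dur_s = 2) {
  tymp <- render_tympanal(scene, model, seed = seed)
  w <- trill_windows(signal_onset_s, signal_dur_s)
  ea_l <- effective_amplitude(tymp$left, tymp$fs_hz, w$signal, w$masker,
                              ear = "left")
  ea_r <- effective_amplitude(tymp$right, tymp$fs_hz, w$signal, w$masker,
                              ear = "right")
  list(ea_left_db = ea_l$value_db, ea_right_db = ea_r$value_db,
       ivad_lr_db = ea_r$value_db - ea_l$value_db)
}

# One simulated phonotaxis trial: commanded heading from the effective
# interaural difference, executed by the synthetic walker and re-measured
# through the kinematics analysis.
simulate_phonotaxis_trial <- function(scene, model, curve, snr_db,
                                      motor_noise_deg, seed) {
  m <- measure_trial_ivad(scene, model, seed = child_seed(seed, 1))
  with_seed(child_seed(seed, 2), {
    heading_cmd <- simulate_heading(m$ivad_lr_db, curve) +
      stats::rnorm(1, sd = motor_noise_deg)
    latency_ms <- stats::rnorm(1, mean = 56, sd = 3)
    speed <- max(0.5, 3.5 + 0.2 * snr_db + stats::rnorm(1, sd = 0.3))
    tr <- simulate_walk(heading_cmd, duration_s = 5, onset_s = 1.5,
                        latency_ms = latency_ms, offset_s = 3.5,
                        speed_cm_s = speed, noise_px_sd = 0.02,
                        seed = child_seed(seed, 3))
    kin <- trajectory_and_scalars(tr, 1.5, 3.5)
    list(ivad_lr_db = m$ivad_lr_db, heading_cmd_deg = heading_cmd,
         heading_deg = kin$angular_heading_deg,
         latency_ms = kin$latency_ms, distance_cm = kin$total_distance_cm,
         valid = kin$valid)
  })
}

#' Run a simulated experiment
#'
#' Dispatches on `cfg$experiment`; see [experiment_config()]. Deterministic
#' given `cfg$seed`. When `cfg$out_dir` is set, per-trial tables, condition
#' summaries, a machine-readable JSON manifest, a stage log, and (optional)
#' figures are written there; every table in the manifest can be
#' regenerated from the configuration it echoes.
#'
#' @param cfg An [experiment_config()].
#' @return An object of class `experiment_result`: `tables` (data.frames),
#'   `stats`, and `manifest`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  note("experiment=%s seed=%d n=%d", cfg$experiment, cfg$seed,
       if (cfg$experiment == "nerve") cfg$n_units else cfg$n_flies)
  res <- switch(cfg$experiment,
                exp1_thresholds = run_exp1(cfg, note),
                exp2_snr_separation = run_exp2(cfg, note),
                exp3_symmetry = run_exp3(cfg, note),
                ldv = run_ldv(cfg, note),
                nerve = run_nerve(cfg, note))
  res$log <- log_lines
  res$manifest <- c(list(experiment = cfg$experiment, seed = cfg$seed,
                         parameters = config_echo(cfg)),
                    res$manifest)
  out <- structure(res, class = "experiment_result")
  if (!is.null(cfg$out_dir)) write_experiment_outputs(out, cfg)
  out
}

config_echo <- function(cfg) {
  e <- unclass(cfg)
  e$curve <- unclass(e$curve)
  e$out_dir <- NULL
  e$make_figures <- NULL
  e
}

fly_criteria <- function(cfg) {
  with_seed(child_seed(cfg$seed, 999),
            stats::rnorm(cfg$n_flies, mean = cfg$criterion_db, sd = 0.3))
}

run_exp2 <- function(cfg, note) {
  model <- ear_gain_model(cfg$curve, cfg$meas_noise_db)
  rows <- list()
  k <- 0
  for (fly in seq_len(cfg$n_flies)) for (sep in cfg$separations)
    for (snr in cfg$snrs) for (rep in seq_len(cfg$reps)) {
      k <- k + 1
      side <- if (rep %% 2 == 1) "right" else "left"
      az <- if (side == "right") sep else -sep
      seed <- child_seed(cfg$seed, k)
      scene <- behaviour_scene(cfg$signal_db, cfg$signal_db - snr, az,
                               fs_hz = cfg$fs_hz, noise_seed = seed)
      tr <- simulate_phonotaxis_trial(scene, model, cfg$curve, snr,
                                      cfg$motor_noise_deg, seed)
      rows[[k]] <- data.frame(fly = fly, separation_deg = sep, snr_db = snr,
                              rep = rep, masker_side = side,
                              ivad_lr_db = tr$ivad_lr_db,
                              heading_deg = tr$heading_deg,
                              latency_ms = tr$latency_ms,
                              distance_cm = tr$distance_cm,
                              valid = tr$valid)
    }
  trials <- do.call(rbind, rows)
  note("exp2: %d trials", nrow(trials))
  summ <- do.call(rbind, lapply(split(trials, trials[c("separation_deg", "snr_db")]),
    function(d) {
      mm <- mirror_and_average(d)
      data.frame(separation_deg = d$separation_deg[1], snr_db = d$snr_db[1],
                 mean_heading_deg = mm$mean_deg, sem_heading_deg = mm$sem_deg,
                 mean_distance_cm = mean(d$distance_cm),
                 mean_latency_ms = mean(d$latency_ms), n_flies = mm$n_flies)
    }))
  rownames(summ) <- NULL
  h_mirrored <- ifelse(trials$masker_side == "left",
                       -trials$heading_deg, trials$heading_deg)
  anova <- if (length(unique(trials$separation_deg)) > 1 &&
               length(unique(trials$snr_db)) > 1) {
    circular_anova_hk(h_mirrored, trials$separation_deg, trials$snr_db)
  } else {
    note("exp2: heading ANOVA skipped (needs 2+ levels per factor)")
    NULL
  }
  list(tables = list(trials = trials, summary = summ),
       stats = list(heading_anova = anova),
       manifest = list(summary = split(summ, seq_len(nrow(summ)))))
}

exp3_conditions <- function(separations) {
  conds <- list(list(name = "signal_alone", az = numeric(0), coh = FALSE))
  for (sep in separations) {
    conds <- c(conds, list(
      list(name = sprintf("asym%dR", sep), az = sep, coh = FALSE),
      list(name = sprintf("asym%dL", sep), az = -sep, coh = FALSE),
      list(name = sprintf("sym%d", sep), az = c(-sep, sep), coh = TRUE)))
  }
  conds
}

run_exp3 <- function(cfg, note) {
  model <- ear_gain_model(cfg$curve, cfg$meas_noise_db)
  conds <- exp3_conditions(cfg$separations)
  rows <- list()
  k <- 0
  for (fly in seq_len(cfg$n_flies)) for (ci in seq_along(conds))
    for (rep in seq_len(cfg$reps)) {
      k <- k + 1
      cond <- conds[[ci]]
      seed <- child_seed(cfg$seed, 10000 + k)
      # two coherent maskers each 6 dB below the single-masker level, so
      # their in-phase sum matches the single masker's overall level
      mlev <- if (length(cond$az) == 2) cfg$masker_db - 6.02 else cfg$masker_db
      scene <- behaviour_scene(cfg$signal_db,
                               if (length(cond$az)) mlev else NULL,
                               cond$az, coherent = cond$coh,
                               fs_hz = cfg$fs_hz, noise_seed = seed)
      tr <- simulate_phonotaxis_trial(scene, model, cfg$curve, 0,
                                      cfg$motor_noise_deg, seed)
      rows[[k]] <- data.frame(fly = fly, condition = cond$name, rep = rep,
                              ivad_lr_db = tr$ivad_lr_db,
                              heading_deg = tr$heading_deg,
                              distance_cm = tr$distance_cm,
                              valid = tr$valid)
    }
  trials <- do.call(rbind, rows)
  note("exp3: %d trials", nrow(trials))
  summ <- do.call(rbind, lapply(split(trials, trials$condition), function(d)
    data.frame(condition = d$condition[1],
               mean_heading_deg = circ_mean_deg(d$heading_deg),
               sem_heading_deg = circ_sem_deg(
                 vapply(split(d$heading_deg, d$fly), circ_mean_deg,
                        numeric(1))),
               n_trials = nrow(d))))
  rownames(summ) <- NULL
  get_h <- function(cond) trials$heading_deg[trials$condition == cond]
  stats <- list()
  enough <- cfg$n_flies * cfg$reps >= 4
  if (enough) {
    for (sep in cfg$separations) {
      nm <- sprintf("sym%d_vs_alone", sep)
      stats[[nm]] <- watson_u2(get_h(sprintf("sym%d", sep)),
                               get_h("signal_alone"))
    }
    if (all(c(6, 90) %in% cfg$separations))
      stats$asym90R_vs_asym6R <- watson_u2(get_h("asym90R"), get_h("asym6R"))
  } else {
    note("exp3: heading comparisons skipped (fewer than 4 trials/condition)")
  }
  list(tables = list(trials = trials, summary = summ), stats = stats,
       manifest = list(summary = split(summ, seq_len(nrow(summ)))))
}

run_exp1 <- function(cfg, note) {
  model <- ear_gain_model(cfg$curve, cfg$meas_noise_db)
  crit <- fly_criteria(cfg)
  conds <- data.frame(condition = c("quiet", paste0("sep", cfg$separations)),
                      sep = c(NA, cfg$separations))
  rows <- list()
  k <- 0
  for (fly in seq_len(cfg$n_flies)) for (ci in seq_len(nrow(conds))) {
    k <- k + 1
    sep <- conds$sep[ci]
    base_seed <- child_seed(cfg$seed, 20000 + k)
    trial_no <- 0
    observer <- function(level_db) {
      trial_no <<- trial_no + 1
      seed <- child_seed(base_seed, trial_no)
      scene <- behaviour_scene(level_db,
                               if (is.na(sep)) NULL else cfg$masker_db,
                               if (is.na(sep)) numeric(0) else sep,
                               fs_hz = cfg$fs_hz, noise_seed = seed)
      m <- measure_trial_ivad(scene, model, seed = child_seed(seed, 4))
      best <- max(m$ea_left_db, m$ea_right_db)
      with_seed(child_seed(seed, 5),
                stats::runif(1) < stats::plogis((best - crit[fly]) / 0.3))
    }
    st <- run_staircase(observer, staircase_config())
    rows[[k]] <- data.frame(fly = fly, condition = conds$condition[ci],
                            threshold_db = st$threshold_db,
                            ub_db = st$ub_db, lb_db = st$lb_db,
                            flag = st$flag, n_trials = nrow(st$log))
  }
  thresholds <- do.call(rbind, rows)
  note("exp1: %d staircases", nrow(thresholds))
  cmp <- compare_masked_thresholds(thresholds)
  list(tables = list(thresholds = thresholds, summary = cmp$summary),
       stats = cmp,
       manifest = list(summary = split(cmp$summary, seq_len(nrow(cmp$summary))),
                       srm_90_minus_6_db = cmp$srm_90_minus_6_db))
}

#' Compare masked behavioural thresholds across masker configurations
#'
#' Summarizes quiet / small-separation / large-separation thresholds and
#' reports the spatial-release contrast (90 minus 6 degree threshold,
#' within fly) with a confidence interval. No claim is made that the
#' simulation must reproduce any particular contrast; the function reports
#' whatever the configured model yields.
#'
#' @param thresholds A data.frame with columns `fly`, `condition`
#'   (`"quiet"`, `"sep6"`, `"sep90"`), `threshold_db` (as produced by the
#'   threshold experiment).
#' @return A list: `summary` (per-condition mean/SD/n),
#'   `srm_90_minus_6_db` (mean within-fly difference), `srm_ci` (95% CI),
#'   and `masked_minus_quiet_db`.
#' @export
compare_masked_thresholds <- function(thresholds) {
  ok <- !is.na(thresholds$threshold_db)
  d <- thresholds[ok, ]
  summary <- do.call(rbind, lapply(split(d, d$condition), function(x)
    data.frame(condition = x$condition[1],
               mean_db = mean(x$threshold_db),
               sd_db = stats::sd(x$threshold_db), n = nrow(x))))
  rownames(summary) <- NULL
  wide <- function(cond) {
    v <- d$threshold_db[d$condition == cond]
    names(v) <- d$fly[d$condition == cond]
    v
  }
  out <- list(summary = summary, srm_90_minus_6_db = NA_real_,
              srm_ci = c(NA_real_, NA_real_),
              masked_minus_quiet_db = NA_real_)
  if (all(c("sep6", "sep90") %in% d$condition)) {
    t6 <- wide("sep6"); t90 <- wide("sep90")
    flies <- intersect(names(t6), names(t90))
    diffs <- t90[flies] - t6[flies]
    out$srm_90_minus_6_db <- mean(diffs)
    if (length(diffs) > 1 && stats::sd(diffs) > 0) {
      tt <- stats::t.test(diffs)
      out$srm_ci <- as.numeric(tt$conf.int)
    }
  }
  if ("quiet" %in% d$condition && any(d$condition != "quiet")) {
    out$masked_minus_quiet_db <-
      mean(d$threshold_db[d$condition != "quiet"]) -
      mean(d$threshold_db[d$condition == "quiet"])
  }
  out
}

run_ldv <- function(cfg, note) {
  model <- ear_gain_model(cfg$curve, cfg$meas_noise_db)
  # directionality calibration: single trill source swept across azimuth
  cal_az <- seq(-90, 90, by = 15)
  cal <- vapply(seq_along(cal_az), function(i) {
    scene <- behaviour_scene(cfg$signal_db, fs_hz = cfg$fs_hz,
                             noise_seed = child_seed(cfg$seed, 30000 + i))
    scene$azimuths_deg[1] <- cal_az[i]
    measure_trial_ivad(scene, model,
                       seed = child_seed(cfg$seed, 31000 + i))$ivad_lr_db
  }, numeric(1))
  fit <- fit_sigmoid(cal_az, cal)
  note("ldv: calibration over %d azimuths, rss %.3g", length(cal_az), fit$rss)
  rows <- list()
  k <- 0
  for (snr in cfg$snrs) for (sweep in seq_len(3)) {
    k <- k + 1
    seed <- child_seed(cfg$seed, 32000 + k)
    scene <- behaviour_scene(cfg$masker_db + snr, cfg$masker_db, 90,
                             fs_hz = cfg$fs_hz, noise_seed = seed)
    m <- measure_trial_ivad(scene, model, seed = child_seed(seed, 4))
    rows[[k]] <- data.frame(snr_db = snr, sweep = sweep,
                            ea_ipsi_db = m$ea_right_db,
                            ea_contra_db = m$ea_left_db,
                            ivad_lr_db = m$ivad_lr_db)
  }
  sweeps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(sweeps, sweeps$snr_db), function(d) {
    ivad <- mean(d$ivad_lr_db)
    data.frame(snr_db = d$snr_db[1], mean_ea_ipsi_db = mean(d$ea_ipsi_db),
               mean_ea_contra_db = mean(d$ea_contra_db),
               mean_ivad_lr_db = ivad,
               predicted_direction_deg = predict_direction(ivad, fit))
  }))
  rownames(summ) <- NULL
  list(tables = list(calibration = data.frame(azimuth_deg = cal_az,
                                              ivad_lr_db = cal),
                     sweeps = sweeps, summary = summ),
       stats = list(directionality_fit = fit),
       manifest = list(fit_par = as.list(fit$par),
                       summary = split(summ, seq_len(nrow(summ)))))
}

# The 2-pulse nerve protocol within a 1 s acquisition: masker 0.8 s from
# 0.1 s, 40 ms 2-pulse signal at 0.5 s; masker-alone window 60 ms earlier.
nerve_sweep_counts <- function(signal_db, masker_db, cfg, model, seed) {
  sources <- list(source_spec(pulse_train_spec(total_s = 0.04),
                              azimuth_deg = 0, level_db = signal_db,
                              onset_s = 0.5))
  if (!is.null(masker_db))
    sources <- c(sources, list(source_spec(
      noise_spec(total_s = 0.8, rng_seed = child_seed(seed, 1)),
      azimuth_deg = 90, level_db = masker_db, onset_s = 0.1)))
  scene <- assemble_scene(scene_spec(sources, fs_hz = cfg$fs_hz, record_s = 1))
  tymp <- render_tympanal(scene, model, seed = child_seed(seed, 2))
  count_ear <- function(x, ear_k) {
    aff <- spikes_from_trace(x, scene$fs_hz, quiet_s = c(0, 0.1),
                             spec = afferent_spec("I"),
                             seed = child_seed(seed, 3 + ear_k))
    v <- simulate_nerve_voltage(aff, scene$fs_hz, dur_s = 1,
                                noise_sd = 0.12,
                                seed = child_seed(seed, 5 + ear_k))
    det <- detect_impulses(v, quiet_s = c(0, 0.1))
    c(masker = sum(det$times_s >= 0.30 & det$times_s < 0.34),
      signal = sum(det$times_s >= 0.50 & det$times_s < 0.54))
  }
  list(left = count_ear(tymp$left, 0), right = count_ear(tymp$right, 1))
}

run_nerve <- function(cfg, note) {
  model <- ear_gain_model(cfg$curve, cfg$meas_noise_db)
  nerve_snrs <- seq(-18, 6, by = 6)
  rows <- list()
  thr_rows <- list()
  k <- 0
  for (unit in seq_len(cfg$n_units)) {
    da <- list(left = numeric(0), right = numeric(0))
    mlevs <- cfg$signal_db - nerve_snrs
    for (li in seq_along(mlevs)) {
      counts <- list(left = matrix(NA_real_, cfg$sweeps, 2),
                     right = matrix(NA_real_, cfg$sweeps, 2))
      for (sw in seq_len(cfg$sweeps)) {
        k <- k + 1
        cc <- nerve_sweep_counts(cfg$signal_db, mlevs[li], cfg, model,
                                 child_seed(cfg$seed, 40000 + k))
        counts$left[sw, ] <- cc$left
        counts$right[sw, ] <- cc$right
      }
      for (ear in c("left", "right")) {
        ss <- standard_separation(counts[[ear]][, 1], counts[[ear]][, 2])
        da[[ear]] <- c(da[[ear]], ss$d_a)
        rows[[length(rows) + 1]] <- data.frame(
          unit = unit, ear = ear, masker_db = mlevs[li],
          snr_db = nerve_snrs[li],
          mean_masker_count = mean(counts[[ear]][, 1]),
          mean_signal_count = mean(counts[[ear]][, 2]), d_a = ss$d_a)
      }
    }
    for (ear in c("left", "right")) {
      mt <- try(masked_threshold(mlevs, da[[ear]], ear = ear), silent = TRUE)
      thr_rows[[length(thr_rows) + 1]] <- data.frame(
        unit = unit, ear = ear,
        threshold_masker_db = if (inherits(mt, "try-error") || mt$out_of_range)
          NA_real_ else mt$threshold_db)
    }
  }
  da_table <- do.call(rbind, rows)
  thresholds <- do.call(rbind, thr_rows)
  note("nerve: %d units, %d sweeps", cfg$n_units, k)
  # masker at +90: right ear is masker-ipsilateral, left is contralateral
  summ <- do.call(rbind, lapply(split(thresholds, thresholds$ear), function(d)
    data.frame(ear = d$ear[1],
               role = if (d$ear[1] == "right") "ipsi" else "contra",
               mean_threshold_masker_db = mean(d$threshold_masker_db,
                                               na.rm = TRUE),
               n = sum(!is.na(d$threshold_masker_db)))))
  rownames(summ) <- NULL
  list(tables = list(d_a = da_table, thresholds = thresholds, summary = summ),
       stats = list(),
       manifest = list(summary = split(summ, seq_len(nrow(summ)))))
}

write_experiment_outputs <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(res$tables)) {
    f <- file.path(cfg$out_dir, paste0(nm, ".csv"))
    utils::write.csv(res$tables[[nm]], f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  res$manifest$tables <- files
  jsonlite::write_json(res$manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(res$log, file.path(cfg$out_dir, "log.txt"))
  if (isTRUE(cfg$make_figures) && !is.null(res$tables$summary)) {
    grDevices::pdf(file.path(cfg$out_dir, "summary.pdf"), width = 6,
                   height = 4)
    on.exit(grDevices::dev.off())
    s <- res$tables$summary
    ycol <- intersect(c("mean_heading_deg", "mean_db",
                        "mean_threshold_masker_db", "mean_ivad_lr_db"),
                      names(s))[1]
    if (!is.na(ycol)) {
      graphics::barplot(s[[ycol]],
                        names.arg = apply(s[1], 1, paste, collapse = " "),
                        ylab = ycol, las = 2, cex.names = 0.7)
    }
  }
  invisible(res)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %s (seed %s)\n", x$manifest$experiment,
              x$manifest$seed))
  if (!is.null(x$tables$summary)) print(x$tables$summary, row.names = FALSE)
  invisible(x)
}
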