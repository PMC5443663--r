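# Open-loop treadmill phonotaxis kinematics: two-channel pixel increments
# from the optical sensor are converted to steering (x) and forward (y)
# velocities, virtual walking trajectories, and the scalar response
# measures (latency, total distance, angular heading, validity).

#' A treadmill pixel-increment trace
#'
#' @param dx_px Per-sample x (steering) pixel increments; rightward positive.
#' @param dy_px Per-sample y (forward) pixel increments.
#' @param fs_hz Sample rate in Hz (default 2160, the sensor rate).
#' @param cal_cm_per_px Pixel-to-distance calibration constant in cm/px
#'   (default 0.0028; supplied, not estimated, since video calibration is
#'   out of scope).
#' @return An object of class `treadmill_trace`.
#' @export
treadmill_trace <- function(dx_px, dy_px, fs_hz = 2160,
                            cal_cm_per_px = 0.0028) {
  if (length(dx_px) != length(dy_px))
    stop("treadmill_trace: channel lengths differ")
  stopifnot(fs_hz > 0, cal_cm_per_px > 0)
  structure(list(dx_px = as.numeric(dx_px), dy_px = as.numeric(dy_px),
                 fs_hz = fs_hz, cal_cm_per_px = cal_cm_per_px),
            class = "treadmill_trace")
}

#' Read a treadmill trace from a 3-column delimited file
#'
#' @param path File with columns sample_index, dx_px, dy_px.
#' @param fs_hz,cal_cm_per_px Acquisition parameters (see
#'   [treadmill_trace()]).
#' @return A [treadmill_trace()].
#' @export
read_treadmill_trace <- function(path, fs_hz = 2160, cal_cm_per_px = 0.0028) {
  d <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#")
  treadmill_trace(d[[2]], d[[3]], fs_hz = fs_hz,
                  cal_cm_per_px = cal_cm_per_px)
}

#' Steering and forward velocity components
#'
#' Velocities are the calibrated per-sample increments times the sample
#' rate (cm/s): steering from x (rightward positive), forward from y.
#' An optional centred moving average smooths the series.
#'
#' @param trace A [treadmill_trace()].
#' @param smooth_ms Moving-average window in ms (default 50; 0 disables).
#' @return List with `steering_v` and `forward_v` (cm/s), `t_s`, and the
#'   smoothing window used.
#' @export
velocities <- function(trace, smooth_ms = 50) {
  stopifnot(inherits(trace, "treadmill_trace"))
  k <- trace$cal_cm_per_px * trace$fs_hz
  st <- trace$dx_px * k
  fw <- trace$dy_px * k
  w <- round(smooth_ms / 1000 * trace$fs_hz)
  if (w > 1) {
    st <- sliding_mean(st, w)
    fw <- sliding_mean(fw, w)
  }
  list(steering_v = st, forward_v = fw,
       t_s = (seq_along(st) - 1) / trace$fs_hz, smooth_ms = smooth_ms)
}

#' Virtual trajectory and scalar response measures for one trial
#'
#' The virtual path is the cumulative sum of calibrated increments; total
#' distance is the sum of per-sample step lengths. Response latency is the
#' time from signal onset to the first sample at which the forward velocity
#' exceeds 3 times its pre-stimulus SD and stays above it for at least
#' 20 ms. The mid-response angular heading is the direction
#' (atan2(net_x, net_y), degrees, right-positive) of the displacement
#' accumulated from response onset to the temporal midpoint between
#' response onset and signal offset; `heading = "whole"` uses the full
#' response instead. A trial is valid when the total translational movement
#' exceeds 1 cm.
#'
#' @param trace A [treadmill_trace()].
#' @param signal_onset_s,signal_offset_s Stimulus timing from the scene
#'   specification, in seconds.
#' @param heading `"mid"` (default) or `"whole"`.
#' @param latency_mult Velocity-threshold multiple of the pre-stimulus SD
#'   (default 3).
#' @param sustain_ms Minimum supra-threshold duration in ms (default 20).
#' @param smooth_ms Smoothing for the reported velocity components
#'   (default 50).
#' @param latency_smooth_ms Separate light smoothing used only for onset
#'   detection (default 5; a wide centred window would smear the response
#'   onset backwards in time and bias the latency).
#' @return An object of class `trial_kinematics`: `path_xy` (cm),
#'   `total_distance_cm`, `latency_ms`, `angular_heading_deg`, `valid`, and
#'   the velocity components.
#' @export
trajectory_and_scalars <- function(trace, signal_onset_s, signal_offset_s,
                                   heading = c("mid", "whole"),
                                   latency_mult = 3, sustain_ms = 20,
                                   smooth_ms = 50, latency_smooth_ms = 5) {
  stopifnot(inherits(trace, "treadmill_trace"))
  heading <- match.arg(heading)
  fs <- trace$fs_hz
  cal <- trace$cal_cm_per_px
  x <- cumsum(trace$dx_px) * cal
  y <- cumsum(trace$dy_px) * cal
  total <- sum(sqrt(trace$dx_px^2 + trace$dy_px^2)) * cal
  vel <- velocities(trace, smooth_ms = smooth_ms)
  vdet <- velocities(trace, smooth_ms = latency_smooth_ms)$forward_v
  on_i <- max(1, round(signal_onset_s * fs) + 1)
  off_i <- min(length(x), round(signal_offset_s * fs))
  pre <- vdet[seq_len(on_i - 1)]
  sd_pre <- if (length(pre) > 1) stats::sd(pre) else 0
  thr <- latency_mult * sd_pre
  if (thr == 0) thr <- .Machine$double.eps
  need <- max(1, round(sustain_ms / 1000 * fs))
  above <- vdet[on_i:off_i] > thr
  # first run of >= `need` consecutive supra-threshold samples
  latency_ms <- NA_real_
  resp_i <- NA_integer_
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= need)
  if (length(hit)) {
    resp_i <- on_i + starts[hit[1]] - 1
    latency_ms <- (resp_i - on_i) / fs * 1000
  }
  ang <- NA_real_
  if (!is.na(resp_i)) {
    end_i <- if (heading == "mid") round((resp_i + off_i) / 2) else off_i
    net_x <- x[end_i] - x[resp_i]
    net_y <- y[end_i] - y[resp_i]
    if (net_x != 0 || net_y != 0)
      ang <- atan2(net_x, net_y) * 180 / pi
  }
  structure(list(path_xy = cbind(x = x, y = y),
                 steering_v = vel$steering_v, forward_v = vel$forward_v,
                 total_distance_cm = total, latency_ms = latency_ms,
                 angular_heading_deg = ang, heading_mode = heading,
                 valid = total > 1 && !is.na(ang), fs_hz = fs),
            class = "trial_kinematics")
}

#' @export
print.trial_kinematics <- function(x, ...) {
  cat(sprintf(
    "trial_kinematics: distance %.2f cm, latency %s ms, heading (%s) %s deg, %s\n",
    x$total_distance_cm, format(x$latency_ms, digits = 4), x$heading_mode,
    format(x$angular_heading_deg, digits = 4),
    if (x$valid) "valid" else "invalid"))
  invisible(x)
}

#' Mirror left-masker trials and average within, then across, individuals
#'
#' Trials recorded with the masker on the left are mirrored about the 0
#' degree azimuth (heading sign negated) before pooling with right-masker
#' trials. Per-fly circular means are computed first; the condition summary
#' is the circular mean and circular SEM across flies.
#'
#' @param trials A data.frame with columns `fly`, `heading_deg`, and
#'   `masker_side` (`"left"`, `"right"`, or `"none"` for conditions without
#'   a lateralized masker).
#' @return A list: `mean_deg`, `sem_deg`, `n_flies`, and the per-fly means.
#' @export
mirror_and_average <- function(trials) {
  need <- c("fly", "heading_deg", "masker_side")
  if (!all(need %in% names(trials)))
    stop("mirror_and_average: trials need columns fly, heading_deg, masker_side")
  side <- trials$masker_side
  if (any(is.na(side)) || !all(side %in% c("left", "right", "none")))
    stop("mirror_and_average: every trial must be labelled left/right/none")
  h <- ifelse(side == "left", -trials$heading_deg, trials$heading_deg)
  per_fly <- vapply(split(h, trials$fly), circ_mean_deg, numeric(1))
  list(mean_deg = circ_mean_deg(per_fly),
       sem_deg = circ_sem_deg(per_fly),
       n_flies = length(per_fly),
       per_fly_deg = per_fly,
       mirrored_heading_deg = h)
}

#' Simulate a treadmill walk at a commanded heading
#'
#' Generates pixel increments for a tethered walker that is still (sensor
#' noise only) until `onset_s + latency_ms`, then walks at `speed_cm_s`
#' along `heading_deg` until `offset_s`. Used to close the loop from the
#' ear model's heading prediction back through the kinematics analysis.
#'
#' @param heading_deg Commanded heading (degrees, right-positive).
#' @param duration_s Trial length (s).
#' @param onset_s Signal onset (s).
#' @param latency_ms Response latency after onset (default 56 ms).
#' @param offset_s Signal offset; walking stops here (default: end of trial).
#' @param speed_cm_s Walking speed (default 6 cm/s).
#' @param fs_hz,cal_cm_per_px Acquisition parameters.
#' @param noise_px_sd Sensor noise SD in px/sample (default 0).
#' @param seed Optional seed for the sensor noise.
#' @return A [treadmill_trace()].
#' @export
simulate_walk <- function(heading_deg, duration_s, onset_s,
                          latency_ms = 56, offset_s = duration_s,
                          speed_cm_s = 6, fs_hz = 2160,
                          cal_cm_per_px = 0.0028, noise_px_sd = 0,
                          seed = NULL) {
  n <- round(duration_s * fs_hz)
  dx <- numeric(n)
  dy <- numeric(n)
  t0 <- round((onset_s + latency_ms / 1000) * fs_hz) + 1
  t1 <- min(n, round(offset_s * fs_hz))
  if (t0 <= t1) {
    step_px <- speed_cm_s / fs_hz / cal_cm_per_px
    a <- heading_deg * pi / 180
    dx[t0:t1] <- step_px * sin(a)
    dy[t0:t1] <- step_px * cos(a)
  }
  if (noise_px_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(2 * n, sd = noise_px_sd))
    dx <- dx + noise[seq_len(n)]
    dy <- dy + noise[n + seq_len(n)]
  }
  treadmill_trace(dx, dy, fs_hz = fs_hz, cal_cm_per_px = cal_cm_per_px)
}

#' Write a treadmill trace as 3-column delimited text
#'
#' @param trace A [treadmill_trace()].
#' @param path Output path.
#' @export
write_treadmill_trace <- function(trace, path) {
  stopifnot(inherits(trace, "treadmill_trace"))
  utils::write.table(
    data.frame(sample_index = seq_along(trace$dx_px) - 1L,
               dx_px = trace$dx_px, dy_px = trace$dy_px),
    path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
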