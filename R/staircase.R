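# Adaptive descending staircase for behavioural recognition thresholds:
# start at 76 dB, descend in 3 dB steps to the first non-response, probe a
# half step (1.5 dB) up, and average the bracketing levels in the power
# domain.

#' Staircase configuration
#'
#' @param start_db Initial signal level (default 76).
#' @param step_db Descending step size (default 3).
#' @param final_half_step_db Final probe increment (default `step_db / 2`).
#' @param min_db Floor below which the descent aborts (default 10).
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(start_db = 76, step_db = 3,
                             final_half_step_db = step_db / 2, min_db = 10) {
  stopifnot(step_db > 0, min_db < start_db)
  if (abs(final_half_step_db - step_db / 2) > 1e-9)
    stop("staircase_config: final_half_step_db must be step_db/2")
  structure(list(start_db = start_db, step_db = step_db,
                 final_half_step_db = final_half_step_db, min_db = min_db),
            class = "staircase_config")
}

#' Power-domain threshold formula
#'
#' Recognition threshold = 10*log10((10^(UB/10) + 10^(LB/10)) / 2): the
#' bracketing levels are averaged as powers, not as dB, so the result
#' always lies in (LB, UB) and is at least their arithmetic dB mean.
#'
#' @param ub,lb Upper and lower bound levels in dB.
#' @return Threshold in dB.
#' @export
threshold_formula <- function(ub, lb) {
  stopifnot(is.finite(ub), is.finite(lb))
  10 * log10((10^(ub / 10) + 10^(lb / 10)) / 2)
}

#' Deterministic observer with a hard threshold
#'
#' @param threshold_db Responds iff the level is at or above this.
#' @return A function `level -> logical`.
#' @export
observer_deterministic <- function(threshold_db) {
  force(threshold_db)
  function(level_db) level_db >= threshold_db
}

#' Stochastic observer with a logistic psychometric function
#'
#' Response probability is plogis((level - threshold) / slope).
#'
#' @param threshold_db Midpoint of the psychometric function.
#' @param slope_db Logistic scale parameter in dB (smaller = steeper).
#' @return A function `level -> logical` (draws from the session RNG).
#' @export
observer_logistic <- function(threshold_db, slope_db = 1) {
  force(threshold_db); force(slope_db)
  function(level_db) {
    stats::runif(1) < stats::plogis((level_db - threshold_db) / slope_db)
  }
}

#' Run the adaptive descending staircase
#'
#' Descends from `start_db` in `step_db` steps until the first non-response
#' at level L, then probes L + step/2. If the probe elicits a response the
#' probe level is the upper bound (UB) and L the lower bound (LB);
#' otherwise the probe level is the LB and the last responded level
#' (L + step) the UB. The threshold is [threshold_formula()] of the bounds.
#'
#' @param observer A function `level_db -> logical` (e.g.
#'   [observer_deterministic()] or [observer_logistic()]).
#' @param cfg A [staircase_config()].
#' @param seed Optional seed applied around the whole run (for stochastic
#'   observers).
#' @return An object of class `staircase_result` with `ub_db`, `lb_db`,
#'   `threshold_db`, a `flag` (`"ok"`, `"above_range"` if there is no
#'   response at the start level, `"below_range"` if the floor is reached
#'   without a non-response), and the trial `log` (data.frame).
#' @export
run_staircase <- function(observer, cfg = staircase_config(), seed = NULL) {
  stopifnot(inherits(cfg, "staircase_config"))
  with_seed(seed, {
    log <- data.frame(trial = integer(), level_db = numeric(),
                      response = logical(), phase = character())
    add <- function(level, resp, phase) {
      log[nrow(log) + 1L, ] <<- list(nrow(log) + 1L, level, resp, phase)
    }
    out <- function(ub, lb, flag) {
      structure(list(ub_db = ub, lb_db = lb,
                     threshold_db = if (flag == "ok") threshold_formula(ub, lb)
                                    else NA_real_,
                     flag = flag, log = log),
                class = "staircase_result")
    }
    level <- cfg$start_db
    resp <- observer(level)
    add(level, resp, "descent")
    if (!resp) return(out(NA_real_, NA_real_, "above_range"))
    repeat {
      level <- level - cfg$step_db
      if (level < cfg$min_db)
        return(out(NA_real_, NA_real_, "below_range"))
      resp <- observer(level)
      add(level, resp, "descent")
      if (!resp) break
    }
    probe <- level + cfg$final_half_step_db
    presp <- observer(probe)
    add(probe, presp, "probe")
    if (presp) out(probe, level, "ok")
    else out(level + cfg$step_db, probe, "ok")
  })
}

#' @export
print.staircase_result <- function(x, ...) {
  if (x$flag != "ok") {
    cat(sprintf("staircase_result: %s (no threshold)\n", x$flag))
  } else {
    cat(sprintf("staircase_result: UB %.2f, LB %.2f -> threshold %.2f dB (%d trials)\n",
                x$ub_db, x$lb_db, x$threshold_db, nrow(x$log)))
  }
  invisible(x)
}
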