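# Level convention: digital amplitude 1.0 corresponds to 60 dB re the package
# reference. Absolute SPL is never physically calibrated; every analysis in
# the package uses dB differences only, so any monotone convention works.
DB_REF_LEVEL <- 60

#' Convert a level in dB to a digital amplitude
#'
#' The package uses a fixed digital reference: amplitude 1.0 at 60 dB.
#' All analyses depend only on dB differences, so the reference is a
#' bookkeeping convention, not a physical calibration.
#'
#' @param level_db Level in dB re the package reference.
#' @return Linear amplitude (dimensionless).
#' @export
db_to_amp <- function(level_db) 10^((level_db - DB_REF_LEVEL) / 20)

#' Convert a digital amplitude to a level in dB
#'
#' @param amp Linear amplitude (> 0).
#' @return Level in dB re the package reference (amplitude 1.0 = 60 dB).
#' @export
amp_to_db <- function(amp) {
  if (any(amp <= 0)) stop("amplitude must be positive to express in dB")
  DB_REF_LEVEL + 20 * log10(amp)
}

#' Root-mean-square of a numeric vector
#'
#' @param x Numeric vector.
#' @return sqrt(mean(x^2)).
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Speed of sound in air
#'
#' @param temp_c Air temperature in degrees Celsius (default 22, typical
#'   laboratory room temperature).
#' @return Speed of sound in m/s.
#' @export
speed_of_sound <- function(temp_c = 22) 331.3 * sqrt(1 + temp_c / 273.15)

#' Best-possible acoustic interaural time difference
#'
#' The largest sound-field ITD available to a pair of ears is the travel
#' time across their separation, attained for a source at 90 degrees off
#' the midline. For Ormia ochracea the tympana are separated by about
#' 500 micrometres, so this is on the order of a microsecond.
#'
#' @param separation_m Ear separation in metres (default 500e-6).
#' @param temp_c Air temperature in degrees Celsius.
#' @return Best-possible ITD in microseconds.
#' @export
best_itd_us <- function(separation_m = 500e-6, temp_c = 22) {
  separation_m / speed_of_sound(temp_c) * 1e6
}

#' Acoustic wavelength of a tone
#'
#' @param freq_hz Frequency in Hz.
#' @param temp_c Air temperature in degrees Celsius.
#' @return Wavelength in centimetres.
#' @export
wavelength_cm <- function(freq_hz, temp_c = 22) {
  speed_of_sound(temp_c) / freq_hz * 100
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible 31-bit child seed from a parent seed and an index.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647L) + 1L
}
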