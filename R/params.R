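#' Scanner parameters
#'
#' Static-field and gyromagnetic constants used to convert chemical-shift
#' offsets (ppm) to absolute frequencies (Hz).
#'
#' @param field_strength Static field in tesla. Default 7, a small-animal
#'   high-field system.
#' @param gyromagnetic_ratio Proton gyromagnetic ratio in MHz/T.
#' @return An object of class `scanner_params` with the water resonance
#'   frequency (`f0_hz`, Hz) precomputed; `f0_hz / 1e6` is Hz per ppm.
#' @export
scanner_params <- function(field_strength = 7, gyromagnetic_ratio = 42.577) {
  stopifnot(is.numeric(field_strength), length(field_strength) == 1L,
            is.finite(field_strength), field_strength > 0,
            is.numeric(gyromagnetic_ratio), gyromagnetic_ratio > 0)
  structure(list(
    field_strength = field_strength,
    gyromagnetic_ratio = gyromagnetic_ratio,
    f0_hz = field_strength * gyromagnetic_ratio * 1e6
  ), class = "scanner_params")
}

#' Convert chemical-shift offsets between ppm and Hz
#'
#' @param x Offsets in ppm (`ppm_to_hz`) or Hz (`hz_to_ppm`).
#' @param scanner A [scanner_params()] object.
#' @return Numeric vector of converted offsets.
#' @export
ppm_to_hz <- function(x, scanner = scanner_params()) {
  x * scanner$field_strength * scanner$gyromagnetic_ratio
}

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(x, scanner = scanner_params()) {
  x / (scanner$field_strength * scanner$gyromagnetic_ratio)
}

#' Saturation-pulse parameters
#'
#' Continuous-wave block presaturation pulse. The acquisition this package
#' models applies a single uninterrupted pulse; respiratory-gated timing is
#' treated as fixed and is not simulated.
#'
#' @param b1_amplitude Saturation field B1 in microtesla. Default 1.7.
#' @param duration Saturation time in seconds. Default 4.
#' @param pulse_shape Only `"continuous-wave block"` is supported.
#' @return An object of class `saturation_params`.
#' @export
saturation_params <- function(b1_amplitude = 1.7, duration = 4,
                              pulse_shape = "continuous-wave block") {
  stopifnot(is.numeric(b1_amplitude), length(b1_amplitude) == 1L,
            is.finite(b1_amplitude), b1_amplitude >= 0,
            is.numeric(duration), length(duration) == 1L,
            is.finite(duration), duration >= 0)
  pulse_shape <- match.arg(pulse_shape, "continuous-wave block")
  structure(list(b1_amplitude = b1_amplitude, duration = duration,
                 pulse_shape = pulse_shape),
            class = "saturation_params")
}

#' Proton-pool parameters for exchange simulation
#'
#' One pool of the Bloch-McConnell system. The water pool is the observed
#' pool: shift 0 ppm, fraction 1. Solute pools (amide, semisolid MT) carry a
#' proton fraction relative to water, a chemical shift (positive = downfield
#' of water), and a pool-to-water exchange rate; the reverse (water-to-pool)
#' rate follows from detailed balance as `fraction * exchange_rate`.
#'
#' @param name Pool label, one of `"water"`, `"amide"`, `"mt"`.
#' @param t1,t2 Longitudinal/transverse relaxation times in seconds.
#' @param fraction Proton fraction relative to water (water: 1).
#' @param shift Chemical shift in ppm relative to water (water: 0; amide
#'   protons of protein backbones: +3.5).
#' @param exchange_rate Pool-to-water exchange rate in 1/s (water: 0).
#' @return An object of class `pool_params`.
#' @export
pool_params <- function(name = c("water", "amide", "mt"),
                        t1, t2, fraction = 1, shift = 0, exchange_rate = 0) {
  name <- match.arg(name)
  if (!is.numeric(t1) || t1 <= 0 || !is.numeric(t2) || t2 <= 0)
    stop("relaxation times t1 and t2 must be positive", call. = FALSE)
  if (t2 > t1)
    stop("t2 must not exceed t1", call. = FALSE)
  stopifnot(fraction >= 0, is.finite(shift), exchange_rate >= 0)
  if (name == "water" && (shift != 0 || fraction != 1))
    stop("water pool must have shift 0 and fraction 1", call. = FALSE)
  structure(list(name = name, t1 = t1, t2 = t2, fraction = fraction,
                 shift = shift, exchange_rate = exchange_rate),
            class = "pool_params")
}

#' Default two-pool (water + amide) parameter set
#'
#' Tissue-like relaxation at high field with a dilute amide pool +3.5 ppm
#' downfield of water in the slow-to-intermediate exchange regime. These
#' defaults place the simulated MTR asymmetry in the few-percent range seen
#' in vivo; they are configurable, not claimed tissue biology.
#'
#' @param amide_fraction Amide proton fraction relative to water.
#' @param amide_rate Amide-to-water exchange rate, 1/s.
#' @return List of [pool_params()], water first.
#' @export
default_pools <- function(amide_fraction = 1e-3, amide_rate = 30) {
  list(
    pool_params("water", t1 = 1.8, t2 = 0.05),
    pool_params("amide", t1 = 1.0, t2 = 0.01, fraction = amide_fraction,
                shift = 3.5, exchange_rate = amide_rate)
  )
}

#' Semisolid magnetization-transfer pool
#'
#' Broad third pool with its center slightly upfield of water, reproducing
#' the intrinsically negative MTR asymmetry of reference tissues such as
#' spinal cord. Off by default in [default_pools()] so that two-pool
#' analytic checks stay clean.
#'
#' @param fraction MT proton fraction relative to water.
#' @param rate MT-to-water exchange rate, 1/s.
#' @param shift Center of the broad line in ppm (negative = upfield).
#' @param t2 Transverse relaxation of the semisolid pool, seconds.
#' @return A [pool_params()] object.
#' @export
mt_pool <- function(fraction = 0.08, rate = 25, shift = -2.4, t2 = 4e-5) {
  pool_params("mt", t1 = 1.0, t2 = t2, fraction = fraction,
              shift = shift, exchange_rate = rate)
}

#' @export
print.scanner_params <- function(x, ...) {
  cat(sprintf("Scanner: %.3g T (water resonance %.2f MHz)\n",
              x$field_strength, x$f0_hz / 1e6))
  invisible(x)
}

#' @export
print.saturation_params <- function(x, ...) {
  cat(sprintf("Saturation: %s, B1 = %.3g uT, duration = %.3g s\n",
              x$pulse_shape, x$b1_amplitude, x$duration))
  invisible(x)
}

#' @export
print.pool_params <- function(x, ...) {
  cat(sprintf("Pool %-5s T1 = %.3g s, T2 = %.3g s, f = %.3g, shift = %+.2f ppm, k = %.3g /s\n",
              x$name, x$t1, x$t2, x$fraction, x$shift, x$exchange_rate))
  invisible(x)
}

.check_pools <- function(pools) {
  if (!length(pools))
    stop("at least one pool is required", call. = FALSE)
  if (!all(vapply(pools, inherits, logical(1), "pool_params")))
    stop("pools must be a list of pool_params objects", call. = FALSE)
  names <- vapply(pools, `[[`, character(1), "name")
  if (!"water" %in% names)
    stop("a water pool is required", call. = FALSE)
  if (anyDuplicated(names))
    stop("duplicate pool names", call. = FALSE)
  # water first, fixed ordering for the state vector
  pools[order(names != "water")]
}
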