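# Laboratory device configurations and the perfect-intensity -> realistic
# measurement chain: resolution smearing then counting statistics.

#' Construct a measured or simulated 1D SAXS curve
#'
#' @param q Scattering vector values in A^-1, strictly increasing.
#' @param intensity Intensity in cm^-1, same length as `q`.
#' @param sigma Optional 1-sigma uncertainties in cm^-1.
#' @param config_id Optional instrument tag.
#' @return Object of class `saxs_curve` (a list with fields `q`,
#'   `intensity`, `sigma`, `config_id`).
#' @export
saxs_curve <- function(q, intensity, sigma = NULL, config_id = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) {
    stop("q and intensity must have the same length", call. = FALSE)
  }
  if (length(q) > 1 && any(diff(q) <= 0)) {
    stop("q must be strictly increasing", call. = FALSE)
  }
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) {
      stop("sigma must match q in length", call. = FALSE)
    }
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 config_id = config_id), class = "saxs_curve")
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat("<saxs_curve> ", length(x$q), " points, q in [",
      signif(min(x$q), 4), ", ", signif(max(x$q), 4), "] A^-1",
      if (!is.null(x$config_id)) paste0(", config ", x$config_id), "\n",
      sep = "")
  invisible(x)
}

#' Instrument configuration for a benchtop SAXS device
#'
#' @param name Configuration label.
#' @param sample_detector_distance Sample-to-detector distance, mm.
#' @param wavelength X-ray wavelength, A.
#' @param q_min,q_max Grid endpoints, A^-1.
#' @param delta_q Nominal sampling step, A^-1.
#' @param beam_fwhm FWHM of the incident beam profile in q, A^-1.
#' @param transmitted_flux Transmitted photon flux, photons/s.
#' @param counting_time Counting time, s.
#' @param n_points Grid length; the actual grid is `n_points` values evenly
#'   spaced on `[q_min, q_max]`.
#' @param counts_scale Conversion from cm^-1 to expected detector counts per
#'   bin over the full counting time (absorbs solid angle, sample thickness
#'   and efficiency); `NULL` uses a calibration in which a flat water-like
#'   background of 0.016 cm^-1 collects 200 counts per bin.
#' @param meta Optional list of free-form metadata.
#' @return Object of class `instrument_config`.
#' @export
instrument_config <- function(name, sample_detector_distance, wavelength,
                              q_min, q_max, delta_q, beam_fwhm,
                              transmitted_flux, counting_time, n_points,
                              counts_scale = NULL, meta = list()) {
  if (q_min >= q_max) stop("q_min must be < q_max", call. = FALSE)
  if (delta_q <= 0) stop("delta_q must be > 0", call. = FALSE)
  if (transmitted_flux <= 0 || counting_time <= 0) {
    stop("flux and counting time must be > 0", call. = FALSE)
  }
  if (abs((q_max - q_min) / delta_q + 1 - n_points) > 1) {
    stop("n_points inconsistent with (q_max - q_min)/delta_q + 1",
         call. = FALSE)
  }
  if (is.null(counts_scale)) {
    # counts/bin = I * flux * time * k; calibrate k so 0.016 cm^-1 -> 200
    counts_scale <- 200 / (0.016 * transmitted_flux * counting_time)
  }
  structure(list(name = name,
                 sample_detector_distance = sample_detector_distance,
                 wavelength = wavelength, q_min = q_min, q_max = q_max,
                 delta_q = delta_q, beam_fwhm = beam_fwhm,
                 transmitted_flux = transmitted_flux,
                 counting_time = counting_time, n_points = n_points,
                 counts_scale = counts_scale, meta = meta),
            class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  cat("<instrument_config> ", x$name, "\n", sep = "")
  cat("  q: [", x$q_min, ", ", x$q_max, "] A^-1, ", x$n_points,
      " points (dq ~ ", signif(x$delta_q, 3), ")\n", sep = "")
  cat("  beam FWHM ", x$beam_fwhm, " A^-1, flux ",
      format(x$transmitted_flux, scientific = TRUE), " ph/s, time ",
      x$counting_time, " s\n", sep = "")
  invisible(x)
}

#' The q grid of an instrument configuration
#' @param config An [instrument_config()].
#' @return Numeric vector of length `config$n_points`.
#' @export
config_q_grid <- function(config) {
  seq(config$q_min, config$q_max, length.out = config$n_points)
}

#' Built-in benchtop device configurations
#'
#' Two Cu-source laboratory configurations with Eiger1M detectors:
#' \describe{
#'   \item{Xeuss1800HR}{1800 mm sample-detector distance; 890-point grid
#'     from 0.85e-4 to 1511e-4 A^-1 (step ~1.7e-4); beam FWHM 0.0016 A^-1;
#'     transmitted flux 3.43e6 ph/s; counting time 20 min.}
#'   \item{NanoInXiderHR}{938 mm distance; grid from 3.74e-4 to 4527e-4
#'     A^-1 with step ~7.5e-4 (604 points); beam FWHM 0.0024 A^-1; flux
#'     7.22e6 ph/s; counting time 20 min.}
#' }
#' The detector-limited usable ranges (0.0031-0.1493 and 0.0019-0.4452
#' A^-1 respectively) are recorded in `meta$usable_q_range`.
#'
#' @param name `"Xeuss1800HR"` or `"NanoInXiderHR"`.
#' @return An [instrument_config()].
#' @export
builtin_config <- function(name) {
  switch(name,
    Xeuss1800HR = instrument_config(
      name = "Xeuss1800HR", sample_detector_distance = 1800,
      wavelength = 1.54, q_min = 0.85e-4, q_max = 1511e-4,
      delta_q = 1.7e-4, beam_fwhm = 0.0016,
      transmitted_flux = 3.43e6, counting_time = 1200, n_points = 890,
      meta = list(detector = "Eiger1M",
                  usable_q_range = c(0.0031, 0.1493))),
    NanoInXiderHR = instrument_config(
      name = "NanoInXiderHR", sample_detector_distance = 938,
      wavelength = 1.54, q_min = 3.74e-4, q_max = 4527e-4,
      delta_q = 7.5e-4, beam_fwhm = 0.0024,
      transmitted_flux = 7.22e6, counting_time = 1200, n_points = 604,
      meta = list(detector = "Eiger1M",
                  usable_q_range = c(0.0019, 0.4452))),
    stop("unknown configuration '", name, "'; available: Xeuss1800HR, ",
         "NanoInXiderHR", call. = FALSE))
}

#' Gaussian resolution smearing of a curve
#'
#' Convolves the intensity with a unit-mass Gaussian of the given FWHM on
#' the curve's (uniform) q grid, using reflect padding at the edges so that
#' flat signals are preserved and no intensity is lost at the Guinier end.
#' `beam_fwhm = 0` is the identity.
#'
#' @param curve A [saxs_curve()] on a uniform grid.
#' @param beam_fwhm Beam FWHM in A^-1, >= 0.
#' @return Smeared [saxs_curve()].
#' @export
smear <- function(curve, beam_fwhm) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (beam_fwhm < 0) stop("beam_fwhm must be >= 0", call. = FALSE)
  if (beam_fwhm == 0) return(curve)
  dq <- diff(curve$q)
  if (max(dq) - min(dq) > 1e-6 * mean(dq)) {
    stop("smear() requires a uniform q grid", call. = FALSE)
  }
  h <- mean(dq)
  sd_bins <- beam_fwhm / (2 * sqrt(2 * log(2))) / h
  half <- max(1L, ceiling(4 * sd_bins))
  kern <- stats::dnorm(seq(-half, half), sd = sd_bins)
  kern <- kern / sum(kern)
  n <- length(curve$intensity)
  if (half >= n) stop("smearing kernel wider than the curve", call. = FALSE)
  padded <- c(curve$intensity[(half + 1):2],          # reflect left
              curve$intensity,
              curve$intensity[(n - 1):(n - half)])    # reflect right
  sm <- stats::filter(padded, kern, sides = 2)
  saxs_curve(curve$q, as.numeric(sm[(half + 1):(half + n)]),
             sigma = curve$sigma, config_id = curve$config_id)
}

#' Add Poisson counting noise to a curve
#'
#' Converts intensity to expected detector counts per bin,
#' lambda_j = I_j x flux x time x counts_scale, draws Poisson counts and
#' converts back, attaching sigma = sqrt(counts) on the same scale.
#'
#' @param curve A [saxs_curve()] with non-negative intensity.
#' @param config An [instrument_config()].
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @return [saxs_curve()] with noisy intensity and `sigma`.
#' @export
add_counting_noise <- function(curve, config, seed = NULL) {
  stopifnot(inherits(curve, "saxs_curve"),
            inherits(config, "instrument_config"))
  if (any(curve$intensity < 0)) {
    stop("intensity must be >= 0 before counting noise", call. = FALSE)
  }
  k <- config$transmitted_flux * config$counting_time * config$counts_scale
  lambda <- curve$intensity * k
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  counts <- stats::rpois(length(lambda), lambda)
  saxs_curve(curve$q, counts / k, sigma = sqrt(counts) / k,
             config_id = config$name)
}

#' Simulate a laboratory measurement of a particle population
#'
#' Full chain: absolute model intensity on the configuration grid
#' ([polydisperse_intensity()]), beam smearing ([smear()]), then counting
#' noise ([add_counting_noise()]).
#'
#' @param model A [particle_model()].
#' @param config An [instrument_config()].
#' @param seed Integer seed for the noise draw.
#' @param noiseless If `TRUE`, skip the noise step and return the smeared
#'   curve with `sigma = 0`.
#' @param n_quad,n_pd Quadrature orders passed to
#'   [polydisperse_intensity()].
#' @return A [saxs_curve()] tagged with the configuration name.
#' @export
simulate_measurement <- function(model, config, seed = NULL,
                                 noiseless = FALSE, n_quad = 76, n_pd = 15) {
  q <- config_q_grid(config)
  ideal <- saxs_curve(q, polydisperse_intensity(model, q, n_quad = n_quad,
                                                n_pd = n_pd),
                      config_id = config$name)
  sm <- smear(ideal, config$beam_fwhm)
  if (noiseless) {
    sm$sigma <- rep(0, length(q))
    return(sm)
  }
  add_counting_noise(sm, config, seed = seed)
}
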