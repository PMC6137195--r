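#' Instrument response functions
#'
#' Constructors for the excitation-pulse/instrument response function (IRF)
#' on a given time grid. The IRF is normalised to unit sum before it is used
#' as a convolution kernel. The Gaussian form (default FWHM 1 ns, typical for
#' a pulsed 370 nm LED) is the default; delta and boxcar forms exist mainly
#' for analytic checks.
#'
#' @param time_ns uniform, strictly increasing time grid (ns).
#' @param counts nonnegative kernel values with positive total.
#' @return An object of class `"irf"` with fields `time_ns`, `counts`.
#' @export
irf <- function(time_ns, counts) {
  check_uniform_grid(time_ns, "time")
  if (length(counts) != length(time_ns)) stop_arg("irf grid/counts mismatch")
  if (any(counts < 0) || sum(counts) <= 0) {
    stop_arg("irf counts must be nonnegative with positive total")
  }
  structure(list(time_ns = as.numeric(time_ns), counts = as.numeric(counts)),
            class = "irf")
}

#' @rdname irf
#' @param center pulse centre (ns).
#' @param fwhm full width at half maximum (ns).
#' @export
irf_gaussian <- function(time_ns, center = time_ns[1] + 1, fwhm = 1) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  irf(time_ns, exp(-0.5 * ((time_ns - center) / sigma)^2))
}

#' @rdname irf
#' @param at time (ns) of the single nonzero channel (nearest grid point).
#' @export
irf_delta <- function(time_ns, at = time_ns[1]) {
  counts <- numeric(length(time_ns))
  counts[which.min(abs(time_ns - at))] <- 1
  irf(time_ns, counts)
}

#' @rdname irf
#' @param start start of the flat pulse (ns).
#' @param width pulse width (ns).
#' @export
irf_boxcar <- function(time_ns, start = time_ns[1], width) {
  counts <- as.numeric(time_ns >= start & time_ns < start + width)
  irf(time_ns, counts)
}

# Unit-sum kernel, optionally shifted by `shift` ns (linear interpolation,
# zero outside the grid). Positive shift moves the pulse later.
irf_kernel <- function(x, shift = 0) {
  k <- x$counts
  if (shift != 0) {
    k <- stats::approx(x$time_ns, x$counts, xout = x$time_ns - shift,
                       yleft = 0, yright = 0)$y
  }
  s <- sum(k)
  if (s <= 0) stop_arg("irf shift pushed the pulse off the time grid")
  k / s
}

#' Describe the measurement instrument
#'
#' Wavelength and decay-time grids, excitation source, IRF, counting scale and
#' noise model of a simulated TRES acquisition. The default grids reproduce
#' the published cube geometry: emission 380-600 nm at 5 nm on a half-open
#' grid (44 channels) and a 100-channel 0.05 ns decay window with the
#' excitation pulse near the window start.
#'
#' @param emission_nm strictly increasing, uniformly spaced wavelengths (nm).
#' @param time_ns strictly increasing, uniformly spaced decay times (ns).
#' @param excitation_nm excitation wavelength (nm), default 370.
#' @param irf an [irf()] on `time_ns`; default Gaussian, FWHM 1 ns, centred
#'   1 ns after the window start.
#' @param peak_counts expected counts in the brightest channel of a pure
#'   base-oil measurement (> 0).
#' @param noise `"poisson"` for counting noise or `"none"`.
#' @return An object of class `"instrument_model"`.
#' @export
instrument_model <- function(emission_nm = seq(380, 595, by = 5),
                             time_ns = seq(0, by = 0.05, length.out = 100),
                             excitation_nm = 370,
                             irf = irf_gaussian(time_ns),
                             peak_counts = 1e4,
                             noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  check_uniform_grid(emission_nm, "emission")
  check_uniform_grid(time_ns, "time")
  if (peak_counts <= 0) stop_arg("peak_counts must be > 0")
  if (!identical(length(irf$time_ns), length(time_ns))) {
    stop_arg("irf must be defined on the instrument time grid")
  }
  structure(
    list(emission_nm = as.numeric(emission_nm), time_ns = as.numeric(time_ns),
         excitation_nm = excitation_nm, irf = irf, peak_counts = peak_counts,
         noise = noise),
    class = "instrument_model"
  )
}

#' Instrument preset for single-decay lifetime measurements
#'
#' A long acquisition axis (default 0-60 ns at 0.05 ns) used when fitting
#' multi-exponential decays, as opposed to the short 100-channel TRES window.
#'
#' @param t_max end of the acquisition axis (ns).
#' @param dt channel width (ns).
#' @param fwhm Gaussian IRF width (ns).
#' @param peak_counts expected peak counts.
#' @param noise noise model.
#' @return An [instrument_model()].
#' @export
decay_instrument <- function(t_max = 60, dt = 0.05, fwhm = 1,
                             peak_counts = 1e4,
                             noise = c("poisson", "none")) {
  tg <- seq(0, t_max, by = dt)
  instrument_model(time_ns = tg, irf = irf_gaussian(tg, center = 1, fwhm = fwhm),
                   peak_counts = peak_counts, noise = match.arg(noise))
}
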