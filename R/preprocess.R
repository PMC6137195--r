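#' Standard normal variate transform
#'
#' Centres a spectrum to mean 0 and scales it to unit sample standard
#' deviation (denominator `n - 1`). Used to remove baseline shifts and global
#' intensity changes before multivariate analysis.
#'
#' @param spectrum numeric vector, length >= 2.
#' @return transformed vector with mean 0 and sample sd 1.
#' @export
snv <- function(spectrum) {
  if (length(spectrum) < 2L) stop_arg("snv needs at least 2 points")
  s <- stats::sd(spectrum)
  if (!is.finite(s) || s == 0) stop_arg("snv: zero-variance input")
  (spectrum - mean(spectrum)) / s
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; the default 5-point quadratic
#' window is the standard mild smoother for emission spectra. Edge channels
#' are handled by evaluating the boundary polynomial fits (via
#' `signal::sgolayfilt`), so polynomials up to `polyorder` pass through
#' unchanged everywhere.
#'
#' @param spectrum numeric vector, length >= `window`.
#' @param window odd window length (default 5).
#' @param polyorder polynomial order, < `window` (default 2).
#' @return smoothed vector, same length.
#' @export
savgol_smooth <- function(spectrum, window = 5, polyorder = 2) {
  if (window %% 2 == 0) stop_arg("window must be odd")
  if (polyorder >= window) stop_arg("polyorder must be < window")
  if (length(spectrum) < window) stop_arg("spectrum shorter than window")
  as.numeric(signal::sgolayfilt(spectrum, p = polyorder, n = window))
}

# J x J linear operator equivalent to savgol_smooth on a length-J vector
# (Savitzky-Golay smoothing is linear, so apply it to the identity once).
savgol_operator <- function(J, window, polyorder) {
  vapply(seq_len(J), function(j) {
    e <- numeric(J); e[j] <- 1
    savgol_smooth(e, window, polyorder)
  }, numeric(J)) # columns are images of basis vectors; operator acts as S %*% x
}

#' Pretreat a TRES cube
#'
#' Applies, in order, an optional standard normal variate correction and
#' Savitzky-Golay smoothing along the emission-wavelength mode.
#' SNV modes:
#' \describe{
#'   \item{`"off"`}{no SNV (the default for cubes fed to PARAFAC; see the
#'     methods vignette for why the per-sample variant is not the default
#'     there).}
#'   \item{`"per_sample"`}{one mean/sd per sample, computed on the unfolded
#'     emission x time matrix; removes global per-sample intensity shifts
#'     while preserving the within-sample decay structure.}
#'   \item{`"per_slice"`}{SNV applied independently to each emission fiber
#'     (fixed sample and time channel); the strict reading of applying SNV
#'     "within the emission mode". Erases decay amplitude information.}
#' }
#' Zero-variance fibers/samples are skipped with a warning.
#'
#' @param cube a [tres_cube()].
#' @param savgol logical, apply Savitzky-Golay smoothing along emission.
#' @param window,polyorder smoothing parameters (defaults 5 and 2).
#' @param snv_mode one of `"off"`, `"per_sample"`, `"per_slice"`.
#' @return a [tres_cube()] of the same shape.
#' @export
pretreat_cube <- function(cube, savgol = TRUE, window = 5, polyorder = 2,
                          snv_mode = c("off", "per_sample", "per_slice")) {
  snv_mode <- match.arg(snv_mode)
  X <- cube$counts
  d <- dim(X)
  if (snv_mode == "per_sample") {
    skipped <- 0L
    for (i in seq_len(d[1])) {
      slab <- X[i, , ]
      s <- stats::sd(as.vector(slab))
      if (!is.finite(s) || s == 0) { skipped <- skipped + 1L; next }
      X[i, , ] <- (slab - mean(slab)) / s
    }
    if (skipped > 0L) warning(sprintf("snv: skipped %d zero-variance sample(s)", skipped))
  } else if (snv_mode == "per_slice") {
    skipped <- 0L
    for (i in seq_len(d[1])) for (k in seq_len(d[3])) {
      v <- X[i, , k]
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) { skipped <- skipped + 1L; next }
      X[i, , k] <- (v - mean(v)) / s
    }
    if (skipped > 0L) warning(sprintf("snv: skipped %d zero-variance fiber(s)", skipped))
  }
  if (isTRUE(savgol)) {
    S <- savgol_operator(d[2], window, polyorder)
    for (i in seq_len(d[1])) X[i, , ] <- S %*% X[i, , ]
  }
  out <- cube
  out$counts <- X
  out
}

#' Equivalent steady-state emission spectra
#'
#' Collapses the decay-time mode of a TRES cube by summation, yielding the
#' emission spectrum a steady-state instrument would record (up to scale):
#' entry `(i, j)` is the time-integrated intensity of sample `i` at
#' wavelength `j`.
#'
#' @param cube a [tres_cube()].
#' @return I x J matrix of integrated intensities.
#' @export
equivalent_steady_state <- function(cube) {
  out <- apply(cube$counts, c(1, 2), sum)
  dimnames(out) <- NULL
  out
}
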