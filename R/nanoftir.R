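#' Interferogram container
#'
#' Build an `interferogram` from raw vectors (see also
#' [render_interferogram()]). The grid stores mirror position; the optical
#' path difference is twice the mirror travel, which is why a scan of
#' length s yields a nominal spectral resolution of 1/(2 s).
#'
#' @param position_um Uniform mirror-position grid in micrometres, from 0.
#' @param detector Detector samples (arb.units).
#' @return Object of class `interferogram`.
#' @export
interferogram <- function(position_um, detector) {
  stopifnot(length(position_um) == length(detector), length(position_um) >= 2)
  structure(list(position_um = position_um, detector = detector,
                 scan_length_um = max(position_um) - min(position_um),
                 n_points = length(position_um)),
            class = "interferogram")
}

#' Fourier-transform an interferogram into a complex spectrum
#'
#' Mean-subtracts, optionally apodizes (Hann), zero-fills by an integer
#' factor and takes the complex one-sided DFT of the asymmetric-Michelson
#' interferogram. No symmetrization or Mertz phase correction is applied:
#' the asymmetric geometry yields amplitude and phase directly. The
#' wavenumber axis is \eqn{\nu_k = k / (2 \Delta x N)} with \eqn{\Delta x}
#' the mirror step (in cm) and N the padded length; the nominal resolution
#' is 1/(2 scan length) -- 14.3 cm-1 for a 350 um scan.
#'
#' @param ig An [interferogram()].
#' @param apodization `"none"` (default, boxcar -- consistent with quoting
#'   the nominal resolution) or `"hann"`.
#' @param zero_fill_factor Integer >= 1; pads to `factor * n_points`.
#' @param harmonic_n Demodulation harmonic carried as metadata.
#' @param band Optional `c(nu_min, nu_max)` crop in cm-1.
#' @return Object of class `complex_spectrum`: `wavenumber` (cm-1), complex
#'   `sigma`, `s_n`, `phi_n` (deg), `harmonic`, `resolution_nominal`,
#'   `scan_length_um`.
#' @export
interferogram_to_spectrum <- function(ig, apodization = c("none", "hann"),
                                      zero_fill_factor = 1, harmonic_n = 2,
                                      band = NULL) {
  apodization <- match.arg(apodization)
  stopifnot(inherits(ig, "interferogram"))
  if (ig$n_points < 64) stop("need at least 64 interferogram points")
  dx <- diff(ig$position_um)
  if (max(abs(dx - dx[1])) > 1e-9 * max(abs(dx)))
    stop("non-uniform mirror-position grid")
  zf <- as.integer(zero_fill_factor)
  if (zf < 1) stop("zero_fill_factor must be an integer >= 1")
  y <- ig$detector - mean(ig$detector)
  n <- length(y)
  if (apodization == "hann")
    y <- y * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  N <- n * zf
  yp <- c(y, rep(0, N - n))
  S <- stats::fft(yp)
  dx_cm <- dx[1] * 1e-4
  k <- 0:(N %/% 2)
  nu <- k / (2 * dx_cm * N)            # factor 2: OPD doubles the mirror path
  sigma <- S[k + 1]
  if (!is.null(band)) {
    keep <- nu >= band[1] & nu <= band[2]
    nu <- nu[keep]; sigma <- sigma[keep]
  }
  structure(list(wavenumber = nu, sigma = sigma, s_n = Mod(sigma),
                 phi_n = Arg(sigma) * 180 / pi, harmonic = harmonic_n,
                 resolution_nominal = 1 / (2 * ig$scan_length_um * 1e-4),
                 scan_length_um = ig$scan_length_um),
            class = "complex_spectrum")
}

#' @export
print.complex_spectrum <- function(x, ...) {
  cat(sprintf("Complex spectrum, %d points %.0f-%.0f cm-1, nominal resolution %.1f cm-1 (harmonic %d)\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              x$resolution_nominal, x$harmonic))
  invisible(x)
}

#' Reference a sample spectrum to a substrate spectrum
#'
#' Per-grid-point complex ratio: amplitude ratio and phase difference.
#' Points where the reference amplitude falls below `floor_frac` times its
#' maximum are masked (band edges carry no usable referencing signal).
#'
#' @param sample,reference `complex_spectrum` objects on identical grids.
#' @param floor_frac Reference-amplitude floor as a fraction of its max.
#' @return A `complex_spectrum` whose `sigma` is the ratio, with `s_n` the
#'   amplitude ratio and `phi_n` the phase difference in degrees; masked
#'   points are NA.
#' @export
reference_spectrum <- function(sample, reference, floor_frac = 0.01) {
  stopifnot(inherits(sample, "complex_spectrum"),
            inherits(reference, "complex_spectrum"))
  if (length(sample$wavenumber) != length(reference$wavenumber) ||
      max(abs(sample$wavenumber - reference$wavenumber)) >
        1e-9 * max(sample$wavenumber))
    stop("sample and reference wavenumber grids differ")
  eta <- sample$sigma / reference$sigma
  eta[Mod(reference$sigma) < floor_frac * max(Mod(reference$sigma))] <-
    NA_complex_
  out <- sample
  out$sigma <- eta
  out$s_n <- Mod(eta)
  out$phi_n <- Arg(eta) * 180 / pi
  out$referenced <- TRUE
  out
}

#' Complex average of repeated spectra
#'
#' Averages the complex-valued \eqn{\sigma_n} per grid point, then splits
#' into amplitude and phase (complex averaging, not amplitude averaging:
#' phase noise partially cancels, as in consecutive-scan averaging).
#'
#' @param spectra Non-empty list of `complex_spectrum` objects on identical
#'   grids.
#' @return A `complex_spectrum`.
#' @export
average_spectra <- function(spectra) {
  if (length(spectra) == 0) stop("empty spectrum list")
  g <- spectra[[1]]$wavenumber
  for (s in spectra)
    if (length(s$wavenumber) != length(g) ||
        max(abs(s$wavenumber - g)) > 1e-9 * max(g))
      stop("all spectra must share one wavenumber grid")
  acc <- Reduce(`+`, lapply(spectra, function(s) s$sigma))
  out <- spectra[[1]]
  out$sigma <- acc / length(spectra)
  out$s_n <- Mod(out$sigma)
  out$phi_n <- Arg(out$sigma) * 180 / pi
  out
}

#' Spectrally averaged (white-light) signal
#'
#' Integrates the amplitude spectrum over a band (trapezoid rule),
#' emulating the zero-path-difference white-light value in which all
#' spectral components of the source contribute.
#'
#' @param spectrum A `complex_spectrum`.
#' @param band Optional `c(nu_min, nu_max)` in cm-1; default full range.
#' @return Scalar integrated amplitude (arb.units x cm-1).
#' @export
white_light_value <- function(spectrum, band = NULL) {
  nu <- spectrum$wavenumber; s <- spectrum$s_n
  if (!is.null(band)) {
    keep <- nu >= band[1] & nu <= band[2]
    nu <- nu[keep]; s <- s[keep]
  }
  if (length(nu) < 2) stop("band too narrow")
  sum(diff(nu) * (s[-1] + s[-length(s)]) / 2)
}
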