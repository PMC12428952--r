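#' @title Fourier optics: pupil function, PSF, OTF
#' @description Fraunhofer propagation of a sampled generalized pupil function
#'   to the point-spread function, and the optical transfer function as the
#'   Fourier transform of the PSF. Angular units are arcminutes in the image
#'   plane and cycles/degree in the frequency plane (1 degree = 60 arcmin;
#'   cutoff frequency f_c = D/lambda cycles/radian, scaled by pi/180 to
#'   cycles/degree).
#' @name fourier_optics
NULL

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 %/% 2 + 1):n1, 1:(n1 %/% 2)), c((n2 %/% 2 + 1):n2, 1:(n2 %/% 2))]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- n1 - n1 %/% 2; s2 <- n2 - n2 %/% 2
  m[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2)]
}

#' Generalized pupil function from a wavefront map
#'
#' P(x, y) = A(x, y) exp(i 2 pi W(x, y) / lambda): unit amplitude inside the
#' pupil, zero outside, with the wavefront OPD W in micrometers converted to
#' phase at the given wavelength.
#'
#' @param wf a [wavefront_map()].
#' @param wavelength_nm wavelength in nanometers (default 555, photopic peak).
#' @return complex square matrix with attributes `pupil_diameter_mm`,
#'   `wavelength_nm`, and `dx_mm` (sample pitch).
#' @export
build_pupil_function <- function(wf, wavelength_nm = 555) {
  stopifnot(inherits(wf, "wavefront_map"), wavelength_nm > 0)
  W <- wf$phase_error_um
  lambda_um <- wavelength_nm / 1000
  phase <- 2 * pi * W / lambda_um
  P <- exp(1i * phase)
  P[is.na(W)] <- 0 + 0i
  attr(P, "pupil_diameter_mm") <- wf$pupil_diameter_mm
  attr(P, "wavelength_nm") <- wavelength_nm
  attr(P, "dx_mm") <- wf$grid_scale_mm_per_sample
  P
}

#' Point-spread function by Fraunhofer propagation
#'
#' Embeds the pupil grid (n samples across the diameter) in an
#' N = n * padding_factor square array, takes |FFT|^2, and normalizes the
#' intensity to unit sum. The angular pitch of one PSF sample is
#' lambda / (N * dx) radians, where dx is the pupil-plane sample pitch;
#' reported in arcminutes.
#'
#' @param pupil complex pupil grid from [build_pupil_function()].
#' @param padding_factor integer >= 2; controls PSF sampling density.
#' @return object of class `psf`: list with `intensity` (centered, unit sum),
#'   `sample_scale_arcmin`, `wavelength_nm`, `pupil_diameter_mm`.
#' @export
compute_psf <- function(pupil, padding_factor = 4) {
  stopifnot(is.complex(pupil), nrow(pupil) == ncol(pupil))
  if (padding_factor < 2) stop("padding_factor must be >= 2")
  n <- nrow(pupil)
  if (n < 64) stop("pupil grid too coarse: need >= 64 samples across the diameter")
  N <- n * padding_factor
  big <- matrix(0 + 0i, N, N)
  i0 <- (N - n) %/% 2
  big[(i0 + 1):(i0 + n), (i0 + 1):(i0 + n)] <- pupil
  field <- stats::fft(big)
  intensity <- fftshift2(Re(field * Conj(field)))
  intensity <- intensity / sum(intensity)
  dx_mm <- attr(pupil, "dx_mm")
  wavelength_nm <- attr(pupil, "wavelength_nm")
  # lambda/(N dx) in radians -> arcmin
  scale_rad <- (wavelength_nm * 1e-9) / (N * dx_mm * 1e-3)
  structure(list(intensity = intensity,
                 sample_scale_arcmin = scale_rad * 180 / pi * 60,
                 wavelength_nm = wavelength_nm,
                 pupil_diameter_mm = attr(pupil, "pupil_diameter_mm")),
            class = "psf")
}

#' Optical transfer function of a PSF
#'
#' OTF as the (inverse-direction) Fourier transform of the PSF intensity,
#' normalized so OTF(0, 0) = 1. Returned centered (zero frequency at
#' element [N/2+1, N/2+1]).
#'
#' @param psf a [compute_psf()] result.
#' @return object of class `otf`: list with complex `values` (centered),
#'   `frequency_scale_cpd` (cycles/degree per sample), `pupil_diameter_mm`,
#'   `wavelength_nm`.
#' @export
compute_otf <- function(psf) {
  stopifnot(inherits(psf, "psf"))
  N <- nrow(psf$intensity)
  vals <- stats::fft(ifftshift2(psf$intensity))
  vals <- fftshift2(vals / vals[1, 1])
  dtheta_rad <- psf$sample_scale_arcmin / 60 * pi / 180
  freq_scale_cpd <- 1 / (N * dtheta_rad) * pi / 180
  structure(list(values = vals,
                 frequency_scale_cpd = freq_scale_cpd,
                 pupil_diameter_mm = psf$pupil_diameter_mm,
                 wavelength_nm = psf$wavelength_nm),
            class = "otf")
}

#' Centered frequency coordinates of an OTF grid (cycles/degree)
#' @param otf an `otf` object.
#' @return list of matrices `fx`, `fy`, `fr` (radial frequency).
#' @export
otf_frequencies <- function(otf) {
  N <- nrow(otf$values)
  f1 <- (seq_len(N) - (N %/% 2 + 1)) * otf$frequency_scale_cpd
  fx <- matrix(f1, N, N)
  fy <- t(fx)
  list(fx = fx, fy = fy, fr = sqrt(fx^2 + fy^2))
}

#' Export a PSF (or OTF modulus) as PNG plus flat binary with JSON sidecar
#'
#' Writes `<basename>.png` (intensity normalized to its maximum; requires the
#' png package), `<basename>.bin` (row-major doubles, little-endian), and
#' `<basename>.json` (grid size and angular/frequency scales).
#'
#' @param x a `psf` or `otf` object.
#' @param basename output path without extension.
#' @return invisibly, the paths written.
#' @export
export_field <- function(x, basename) {
  if (inherits(x, "psf")) {
    m <- x$intensity
    meta <- list(kind = "psf", n = nrow(m),
                 sample_scale_arcmin = x$sample_scale_arcmin,
                 wavelength_nm = x$wavelength_nm,
                 pupil_diameter_mm = x$pupil_diameter_mm)
  } else if (inherits(x, "otf")) {
    m <- Mod(x$values)
    meta <- list(kind = "otf_modulus", n = nrow(m),
                 frequency_scale_cpd = x$frequency_scale_cpd,
                 wavelength_nm = x$wavelength_nm,
                 pupil_diameter_mm = x$pupil_diameter_mm)
  } else stop("x must be a psf or otf object")
  paths <- paste0(basename, c(".png", ".bin", ".json"))
  if (requireNamespace("png", quietly = TRUE)) {
    png::writePNG(m / max(m), paths[1])
  } else {
    paths <- paths[-1]
    warning("png package not available: skipping PNG export")
  }
  con <- file(paste0(basename, ".bin"), "wb")
  writeBin(as.vector(t(m)), con, size = 8, endian = "little")
  close(con)
  writeLines(sprintf(
    '{%s}', paste(sprintf('"%s": %s', names(meta),
                          vapply(meta, function(v) {
                            if (is.character(v)) sprintf('"%s"', v)
                            else format(v, digits = 15)
                          }, character(1))), collapse = ", ")),
    paste0(basename, ".json"))
  invisible(paths)
}

#' Analytic diffraction-limited MTF of a circular aperture
#'
#' (2/pi) (acos(s) - s sqrt(1 - s^2)) with s = f/f_c, zero beyond the cutoff
#' f_c = D/lambda cycles/radian (converted to cycles/degree).
#'
#' @param f_cpd spatial frequency in cycles/degree (vectorized).
#' @param pupil_diameter_mm pupil diameter in mm.
#' @param wavelength_nm wavelength in nm.
#' @return MTF values in `[0, 1]`.
#' @export
diffraction_limited_mtf <- function(f_cpd, pupil_diameter_mm, wavelength_nm = 555) {
  fc_cpd <- (pupil_diameter_mm * 1e-3) / (wavelength_nm * 1e-9) * pi / 180
  s <- pmin(abs(f_cpd) / fc_cpd, 1)
  (2 / pi) * (acos(s) - s * sqrt(1 - s^2))
}
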