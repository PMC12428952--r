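#' @title Zernike wavefront construction
#' @description Constructors and operations for wavefront-error maps built from
#'   OSA/ANSI-indexed Zernike coefficients, object-vergence defocus, and radial
#'   (zonal) lens power profiles. All optical path differences are in
#'   micrometers, radii in millimeters, powers in diopters.
#' @name wavefront
NULL

#' Zernike coefficient set
#'
#' A set of orthonormal (OSA/ANSI) Zernike coefficients defined over a stated
#' pupil diameter. Coefficients are in micrometers of optical path difference.
#'
#' @param n integer vector of radial orders.
#' @param m integer vector of azimuthal frequencies (signed; negative = sine).
#' @param value_um numeric vector of coefficient values in micrometers.
#' @param pupil_diameter_mm positive scalar: the diameter over which the
#'   expansion is normalized.
#' @return An object of class `zernike_coefficients`: a data frame with columns
#'   `n`, `m`, `value_um` and attribute `pupil_diameter_mm`.
#' @examples
#' zernike_coefficients(4, 0, 1.0, pupil_diameter_mm = 6)   # spherical aberration
#' @export
zernike_coefficients <- function(n = integer(), m = integer(),
                                 value_um = numeric(), pupil_diameter_mm) {
  stopifnot(length(n) == length(m), length(m) == length(value_um))
  if (!is.numeric(pupil_diameter_mm) || length(pupil_diameter_mm) != 1 ||
      !is.finite(pupil_diameter_mm) || pupil_diameter_mm <= 0) {
    stop("pupil_diameter_mm must be a positive finite scalar")
  }
  n <- as.integer(n); m <- as.integer(m)
  bad <- n < 0 | abs(m) > n | (n - abs(m)) %% 2L != 0L
  if (any(bad)) {
    stop(sprintf("invalid Zernike index pair(s): %s",
                 paste(sprintf("(%d,%d)", n[bad], m[bad]), collapse = ", ")))
  }
  out <- data.frame(n = n, m = m, value_um = as.numeric(value_um))
  attr(out, "pupil_diameter_mm") <- as.numeric(pupil_diameter_mm)
  class(out) <- c("zernike_coefficients", "data.frame")
  out
}

#' Look up one coefficient (0 if absent)
#' @param z a `zernike_coefficients` object.
#' @param n,m index pair.
#' @return numeric scalar in micrometers.
#' @export
zernike_value <- function(z, n, m) {
  i <- which(z$n == n & z$m == m)
  if (length(i) == 0) 0 else sum(z$value_um[i])
}

# OSA/ANSI single-index j = (n(n+2) + m)/2, used for serialization ordering.
osa_single_index <- function(n, m) (n * (n + 2L) + m) %/% 2L

#' Evaluate one orthonormal Zernike basis polynomial
#'
#' Evaluates the OSA/ANSI orthonormal Zernike polynomial Z(n,m) on normalized
#' pupil coordinates. Values outside the unit disk are zero. Normalization is
#' such that the mean-square value over the unit disk is 1 (piston = 1).
#'
#' @param n radial order (>= 0).
#' @param m signed azimuthal frequency, |m| <= n, n - |m| even. m > 0 selects
#'   the cosine harmonic, m < 0 the sine harmonic.
#' @param x,y numeric arrays of coordinates normalized to unit pupil radius.
#' @return numeric array of the same shape as `x`.
#' @export
evaluate_zernike_basis <- function(n, m, x, y) {
  n <- as.integer(n); m <- as.integer(m)
  if (n < 0 || abs(m) > n || (n - abs(m)) %% 2L != 0L) {
    stop(sprintf("invalid Zernike index pair (%d,%d)", n, m))
  }
  rho <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  am <- abs(m)
  # radial polynomial R_n^|m|
  R <- 0
  for (k in 0:((n - am) / 2)) {
    R <- R + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + am) / 2 - k) * factorial((n - am) / 2 - k)) *
      rho^(n - 2 * k)
  }
  norm <- sqrt(2 * (n + 1) / (1 + (m == 0L)))
  ang <- if (m > 0L) cos(am * theta) else if (m < 0L) sin(am * theta) else 1
  out <- norm * R * ang
  out[rho > 1] <- 0
  out
}

#' Convert object vergence to a Zernike defocus coefficient
#'
#' For a pupil of diameter d, a defocus of V diopters corresponds to a
#' wavefront W = V r^2 / 2 (OPD in micrometers with r in mm), whose
#' least-squares projection onto the orthonormal Z(2,0) basis is
#' c(2,0) = V (d/2)^2 / (4 sqrt(3)).
#'
#' Sign convention: positive object vergence produces a positive c(2,0)
#' (myopic defocus of the retinal image).
#'
#' @param vergence_D object vergence in diopters (vectorized).
#' @param pupil_diameter_mm positive pupil diameter in mm.
#' @return defocus coefficient c(2,0) in micrometers.
#' @seealso [defocus_coefficient_to_vergence()] for the exact inverse.
#' @export
vergence_to_defocus_coefficient <- function(vergence_D, pupil_diameter_mm) {
  if (!is.numeric(pupil_diameter_mm) || any(pupil_diameter_mm <= 0)) {
    stop("pupil_diameter_mm must be positive")
  }
  vergence_D * (pupil_diameter_mm / 2)^2 / (4 * sqrt(3))
}

#' @rdname vergence_to_defocus_coefficient
#' @param c20_um defocus coefficient in micrometers.
#' @export
defocus_coefficient_to_vergence <- function(c20_um, pupil_diameter_mm) {
  if (!is.numeric(pupil_diameter_mm) || any(pupil_diameter_mm <= 0)) {
    stop("pupil_diameter_mm must be positive")
  }
  c20_um * 4 * sqrt(3) / (pupil_diameter_mm / 2)^2
}

#' Radial zonal power profile
#'
#' Describes a lens as contiguous annular zones of constant power, from the
#' pupil center outward (e.g. a center-distance dual-focus design).
#'
#' @param inner_radius_mm,outer_radius_mm,power_D numeric vectors, one entry
#'   per zone. Zones must be contiguous and non-overlapping from radius 0
#'   outward with strictly increasing radii.
#' @param description free-text label.
#' @return An object of class `power_profile` (data frame of zones).
#' @examples
#' power_profile(c(0, 0.75), c(0.75, 1.5), c(0, 1.0), "center-distance dual focus")
#' @export
power_profile <- function(inner_radius_mm, outer_radius_mm, power_D,
                          description = "") {
  stopifnot(length(inner_radius_mm) == length(outer_radius_mm),
            length(outer_radius_mm) == length(power_D),
            length(power_D) >= 1)
  if (inner_radius_mm[1] != 0) stop("first zone must start at radius 0")
  if (any(outer_radius_mm <= inner_radius_mm)) {
    stop("zone radii must be strictly increasing")
  }
  if (length(power_D) > 1 &&
      any(abs(inner_radius_mm[-1] - outer_radius_mm[-length(outer_radius_mm)]) > 1e-12)) {
    stop("zones must be contiguous (each inner radius equals previous outer radius)")
  }
  if (any(!is.finite(power_D))) stop("zone powers must be finite")
  out <- data.frame(inner_radius_mm = inner_radius_mm,
                    outer_radius_mm = outer_radius_mm,
                    power_D = power_D)
  attr(out, "description") <- description
  class(out) <- c("power_profile", "data.frame")
  out
}

#' Square pupil sampling grid
#'
#' Samples the pupil bounding square with `n_samples` points across the
#' diameter, at half-sample-centered coordinates
#' x_i = (i - n/2 + 1/2) * dx. This keeps the grid exactly symmetric under
#' (x, y) -> (-x, -y), so pure-defocus point-spread functions computed on it
#' are exactly even in defocus, and the pupil-edge discontinuity never falls
#' on a lattice point.
#'
#' @param pupil_diameter_mm pupil diameter in mm.
#' @param n_samples samples across the diameter (even integer recommended).
#' @return list with mm coordinate matrices `x`, `y`, normalized radius `rho`,
#'   logical `mask` (inside pupil), and sample pitch `dx_mm`.
#' @export
pupil_grid <- function(pupil_diameter_mm, n_samples) {
  stopifnot(pupil_diameter_mm > 0, n_samples >= 2)
  dx <- pupil_diameter_mm / n_samples
  coord <- (seq_len(n_samples) - n_samples / 2 - 0.5) * dx
  x <- matrix(coord, n_samples, n_samples)
  y <- t(x)
  rho <- sqrt(x^2 + y^2) / (pupil_diameter_mm / 2)
  list(x = x, y = y, rho = rho, mask = rho <= 1, dx_mm = dx)
}

#' Wavefront map
#'
#' A sampled wavefront-error map over the pupil support. `phase_error_um` is a
#' square matrix of OPD in micrometers with `NA` outside the pupil circle.
#'
#' @param phase_error_um square numeric matrix (NA outside the pupil).
#' @param pupil_diameter_mm pupil diameter in mm.
#' @return object of class `wavefront_map`.
#' @export
wavefront_map <- function(phase_error_um, pupil_diameter_mm) {
  stopifnot(is.matrix(phase_error_um), nrow(phase_error_um) == ncol(phase_error_um),
            pupil_diameter_mm > 0)
  structure(list(phase_error_um = phase_error_um,
                 pupil_diameter_mm = as.numeric(pupil_diameter_mm),
                 grid_scale_mm_per_sample = pupil_diameter_mm / nrow(phase_error_um)),
            class = "wavefront_map")
}

#' Convert a zonal power profile to a wavefront map
#'
#' Within each zone the phase error is the natural quadratic continuation
#' P * r^2 / 2 (OPD in micrometers, r in mm, P in diopters) — consistent with
#' [vergence_to_defocus_coefficient()]. No piston adjustment is applied per
#' zone, so discrete power zones produce genuine phase steps at the zone
#' boundaries, as in a center-distance dual-focus lens.
#'
#' @param profile a [power_profile()].
#' @param pupil_diameter_mm analysis pupil diameter; the profile must cover
#'   radius 0 to pupil_diameter_mm/2.
#' @param n_samples grid samples across the pupil diameter.
#' @return a [wavefront_map()].
#' @export
power_profile_to_wavefront <- function(profile, pupil_diameter_mm,
                                       n_samples = 256) {
  stopifnot(inherits(profile, "power_profile"))
  r_max <- max(profile$outer_radius_mm)
  if (r_max < pupil_diameter_mm / 2 - 1e-9) {
    stop(sprintf("power profile covers radius 0-%.3f mm but pupil requires %.3f mm",
                 r_max, pupil_diameter_mm / 2))
  }
  g <- pupil_grid(pupil_diameter_mm, n_samples)
  r_mm <- g$rho * (pupil_diameter_mm / 2)
  phase <- matrix(NA_real_, n_samples, n_samples)
  for (i in seq_len(nrow(profile))) {
    sel <- g$mask & r_mm >= profile$inner_radius_mm[i] &
      (r_mm < profile$outer_radius_mm[i] |
         (i == nrow(profile) & r_mm <= profile$outer_radius_mm[i] + 1e-12))
    phase[sel] <- profile$power_D[i] * r_mm[sel]^2 / 2
  }
  phase[g$mask & is.na(phase)] <- 0  # seam samples between zones, if any
  wavefront_map(phase, pupil_diameter_mm)
}

#' Least-squares Zernike fit of a wavefront map
#'
#' Fits orthonormal Zernike polynomials up to radial order `max_n` to a
#' sampled wavefront map by ordinary least squares on the pupil samples.
#'
#' @param wf a [wavefront_map()].
#' @param max_n maximum radial order to fit.
#' @return a [zernike_coefficients()] at the map's pupil diameter.
#' @export
fit_zernike <- function(wf, max_n = 6) {
  stopifnot(inherits(wf, "wavefront_map"))
  n_samp <- nrow(wf$phase_error_um)
  g <- pupil_grid(wf$pupil_diameter_mm, n_samp)
  xn <- g$x / (wf$pupil_diameter_mm / 2)
  yn <- g$y / (wf$pupil_diameter_mm / 2)
  inside <- g$mask & !is.na(wf$phase_error_um)
  idx <- expand.grid(m = -max_n:max_n, n = 0:max_n)
  idx <- idx[abs(idx$m) <= idx$n & (idx$n - abs(idx$m)) %% 2 == 0, ]
  idx <- idx[order(osa_single_index(idx$n, idx$m)), ]
  A <- vapply(seq_len(nrow(idx)), function(i) {
    evaluate_zernike_basis(idx$n[i], idx$m[i], xn, yn)[inside]
  }, numeric(sum(inside)))
  coef <- stats::lsfit(A, wf$phase_error_um[inside], intercept = FALSE)$coefficients
  zernike_coefficients(idx$n, idx$m, as.numeric(coef), wf$pupil_diameter_mm)
}

#' Rescale Zernike coefficients to a different pupil diameter
#'
#' Rescales a coefficient set defined over one pupil diameter to a smaller
#' concentric analysis pupil by exact disk resampling: the wavefront is
#' evaluated from the original expansion, restricted to the new disk, and
#' refit by least squares. (For the leading term of c(n,0) this reproduces the
#' analytic (d_new/d_old)^n scaling.)
#'
#' @param z a [zernike_coefficients()].
#' @param new_diameter_mm target pupil diameter (<= original).
#' @param n_samples grid resolution for the resampling refit.
#' @return a [zernike_coefficients()] at `new_diameter_mm`.
#' @export
rescale_zernike <- function(z, new_diameter_mm, n_samples = 256) {
  stopifnot(inherits(z, "zernike_coefficients"))
  d_old <- attr(z, "pupil_diameter_mm")
  if (new_diameter_mm > d_old + 1e-9) {
    stop("can only rescale to a smaller or equal pupil diameter")
  }
  if (abs(new_diameter_mm - d_old) < 1e-12) return(z)
  g <- pupil_grid(new_diameter_mm, n_samples)
  # normalized coords w.r.t. the ORIGINAL pupil radius
  xo <- g$x / (d_old / 2); yo <- g$y / (d_old / 2)
  phase <- matrix(0, n_samples, n_samples)
  for (i in seq_len(nrow(z))) {
    phase <- phase + z$value_um[i] * evaluate_zernike_basis(z$n[i], z$m[i], xo, yo)
  }
  phase[!g$mask] <- NA_real_
  fit_zernike(wavefront_map(phase, new_diameter_mm), max_n = max(z$n, 2))
}

#' Compose a total wavefront for one modeled condition
#'
#' Adds (i) a base Zernike expansion (rescaled to the analysis pupil if it was
#' defined at a larger diameter), (ii) defocus from object vergence, and
#' (iii) a zonal power-profile map. Composition is additive in OPD.
#'
#' @param base a [zernike_coefficients()] or NULL.
#' @param vergence_D object vergence in diopters.
#' @param profile a [power_profile()] or NULL.
#' @param pupil_diameter_mm analysis pupil diameter in mm.
#' @param n_samples grid samples across the pupil diameter.
#' @return a [wavefront_map()].
#' @export
compose_wavefront <- function(base = NULL, vergence_D = 0, profile = NULL,
                              pupil_diameter_mm, n_samples = 256) {
  g <- pupil_grid(pupil_diameter_mm, n_samples)
  phase <- matrix(0, n_samples, n_samples)
  if (!is.null(base)) {
    stopifnot(inherits(base, "zernike_coefficients"))
    d_base <- attr(base, "pupil_diameter_mm")
    if (d_base < pupil_diameter_mm - 1e-9) {
      stop(sprintf(
        "base coefficients defined at %.2f mm cannot be extrapolated to %.2f mm",
        d_base, pupil_diameter_mm))
    }
    if (d_base > pupil_diameter_mm + 1e-9) {
      base <- rescale_zernike(base, pupil_diameter_mm, n_samples = n_samples)
    }
    xn <- g$x / (pupil_diameter_mm / 2); yn <- g$y / (pupil_diameter_mm / 2)
    for (i in seq_len(nrow(base))) {
      phase <- phase + base$value_um[i] *
        evaluate_zernike_basis(base$n[i], base$m[i], xn, yn)
    }
  }
  if (vergence_D != 0) {
    r_mm <- g$rho * (pupil_diameter_mm / 2)
    phase <- phase + vergence_D * r_mm^2 / 2
  }
  if (!is.null(profile)) {
    pm <- power_profile_to_wavefront(profile, pupil_diameter_mm, n_samples)
    add <- pm$phase_error_um
    add[is.na(add)] <- 0
    phase <- phase + add
  }
  phase[!g$mask] <- NA_real_
  wavefront_map(phase, pupil_diameter_mm)
}
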