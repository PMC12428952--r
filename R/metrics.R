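#' @title Image-quality metrics: VSOTF, through-focus curves, depth of focus
#' @name metrics
NULL

#' Neural contrast-sensitivity function
#'
#' Radially symmetric parametric neural CSF used as the weighting function
#' inside the visual Strehl ratio. The default is the Mannos-Sakrison form
#' a (b + c f) exp(-(c f)^d), with sensitivity clamped to zero beyond 60
#' cycles/degree (the neural resolution limit). The published through-focus
#' analyses this package follows never state their CSF parameters, so these
#' are frozen package defaults and are carried in the object for logging.
#'
#' @param a,b,c,d parameters of the parametric form.
#' @param cutoff_cpd frequency beyond which sensitivity is zero.
#' @return object of class `neural_csf`.
#' @export
neural_csf <- function(a = 2.6, b = 0.0192, c = 0.114, d = 1.1,
                       cutoff_cpd = 60) {
  structure(list(form = "mannos_sakrison",
                 params = list(a = a, b = b, c = c, d = d),
                 cutoff_cpd = cutoff_cpd),
            class = "neural_csf")
}

#' Evaluate a neural CSF at radial frequency
#' @param csf a [neural_csf()].
#' @param f_cpd radial spatial frequency, cycles/degree (vectorized).
#' @return non-negative sensitivities; 0 beyond the cutoff.
#' @export
csf_eval <- function(csf, f_cpd) {
  stopifnot(inherits(csf, "neural_csf"))
  p <- csf$params
  f <- abs(f_cpd)
  s <- p$a * (p$b + p$c * f) * exp(-(p$c * f)^p$d)
  s[f > csf$cutoff_cpd] <- 0
  pmax(s, 0)
}

#' Visual Strehl ratio of the OTF (VSOTF)
#'
#' VSOTF = integral of CSF(f) |OTF(f)| df over the frequency plane, divided by
#' the same integral for the diffraction-limited OTF of the same pupil
#' diameter and wavelength at zero defocus. Computed by discrete quadrature on
#' the shared frequency grid. The diffraction-limited system scores exactly 1.
#' The ratio is invariant to any uniform rescaling of the CSF.
#'
#' Two numerator variants are implemented. The default weights the OTF
#' modulus (the "frequency-domain" visual Strehl as used in through-focus
#' multifocal/small-aperture modeling, which treats spurious-resolution
#' (phase-reversed) contrast as usable image structure and reproduces the
#' published small-aperture through-focus extents); `numerator = "real"`
#' weights Re\[OTF\] instead (the signed-contrast formulation common in the
#' objective-refraction literature, which penalizes phase reversal).
#'
#' @param otf the test-condition [compute_otf()] result.
#' @param otf_dl the diffraction-limited reference OTF (same pupil diameter,
#'   wavelength, and frequency scaling).
#' @param csf a [neural_csf()].
#' @param numerator `"modulus"` (default) to weight |OTF|, `"real"` to weight
#'   Re\[OTF\].
#' @return scalar VSOTF.
#' @export
vsotf <- function(otf, otf_dl, csf = neural_csf(),
                  numerator = c("modulus", "real")) {
  numerator <- match.arg(numerator)
  stopifnot(inherits(otf, "otf"), inherits(otf_dl, "otf"))
  if (nrow(otf$values) != nrow(otf_dl$values) ||
      abs(otf$frequency_scale_cpd - otf_dl$frequency_scale_cpd) >
        1e-9 * otf$frequency_scale_cpd) {
    stop("test and reference OTFs must share the same frequency grid")
  }
  fr <- otf_frequencies(otf)$fr
  w <- csf_eval(csf, fr)
  num_field <- if (numerator == "modulus") Mod(otf$values) else Re(otf$values)
  sum(w * num_field) / sum(w * Re(otf_dl$values))
}

# OTF of one condition at one vergence (internal pipeline step)
condition_otf <- function(model, vergence_D, wavelength_nm, pupil_samples,
                          padding_factor) {
  wf <- compose_wavefront(base = model$zernike, vergence_D = vergence_D,
                          profile = model$profile,
                          pupil_diameter_mm = model$pupil_diameter_mm,
                          n_samples = pupil_samples)
  P <- build_pupil_function(wf, wavelength_nm)
  compute_otf(compute_psf(P, padding_factor))
}

#' Through-focus VSOTF curve for one modeled condition
#'
#' Sweeps object vergence and computes one VSOTF per vergence. By default each
#' condition is normalized against the diffraction-limited OTF of its OWN
#' pupil diameter (so VSOTF isolates aberration/defocus effects from aperture
#' effects, and an aberration-free condition peaks at exactly 1 at 0 D).
#' Setting `reference_diameter_mm` pins all conditions to one common
#' diffraction-limited reference instead, which materially lowers curves for
#' pupils other than the reference.
#'
#' @param model an [eye_model()].
#' @param vergence_range_D length-2 numeric, e.g. `c(-4, 4)`; must include 0.
#' @param step_D vergence step in diopters (> 0; default 0.05).
#' @param wavelength_nm wavelength (default 555).
#' @param pupil_samples samples across the pupil diameter (default 256).
#' @param padding_factor FFT padding factor (default 4).
#' @param csf a [neural_csf()].
#' @param numerator VSOTF numerator variant, see [vsotf()].
#' @param reference_diameter_mm optional fixed reference pupil diameter; NULL
#'   (default) uses the condition's own diameter.
#' @return a tibble of class `through_focus_curve` with columns `vergence_D`,
#'   `vsotf`, `condition`; grid settings stored in attributes.
#' @export
through_focus_curve <- function(model, vergence_range_D = c(-4, 4),
                                step_D = 0.05, wavelength_nm = 555,
                                pupil_samples = 256, padding_factor = 4,
                                csf = neural_csf(),
                                numerator = c("modulus", "real"),
                                reference_diameter_mm = NULL) {
  numerator <- match.arg(numerator)
  stopifnot(inherits(model, "eye_model"), step_D > 0,
            length(vergence_range_D) == 2)
  if (vergence_range_D[1] > 0 || vergence_range_D[2] < 0) {
    stop("vergence range must include 0 D")
  }
  vergences <- seq(vergence_range_D[1], vergence_range_D[2], by = step_D)
  otf_dl <- condition_otf(eye_model(model$pupil_diameter_mm), 0, wavelength_nm,
                          pupil_samples, padding_factor)
  if (!is.null(reference_diameter_mm) &&
      abs(reference_diameter_mm - model$pupil_diameter_mm) > 1e-9) {
    # a different-diameter pupil has a different frequency pitch, so the
    # fixed reference is evaluated from the analytic circular-aperture MTF
    # on the test condition's own grid
    fr <- otf_frequencies(otf_dl)$fr
    otf_dl$values <- matrix(
      diffraction_limited_mtf(fr, reference_diameter_mm, wavelength_nm) + 0i,
      nrow(fr), ncol(fr))
  }
  vals <- vapply(vergences, function(v) {
    vsotf(condition_otf(model, v, wavelength_nm, pupil_samples, padding_factor),
          otf_dl, csf, numerator = numerator)
  }, numeric(1))
  out <- tibble::tibble(vergence_D = vergences, vsotf = vals,
                        condition = model$label)
  attr(out, "settings") <- list(wavelength_nm = wavelength_nm,
                                pupil_samples = pupil_samples,
                                padding_factor = padding_factor,
                                csf = csf,
                                numerator = numerator,
                                reference_diameter_mm = reference_diameter_mm,
                                pupil_diameter_mm = model$pupil_diameter_mm)
  class(out) <- c("through_focus_curve", class(out))
  out
}

#' Depth of focus at an acceptability threshold
#'
#' Finds the maximal contiguous vergence interval containing the global VSOTF
#' peak over which VSOTF >= threshold. Interval boundaries are refined below
#' the sweep step by linear interpolation between the bracketing samples.
#' Disjoint secondary lobes (e.g. the near peak of a multifocal) are reported
#' separately.
#'
#' @param curve a [through_focus_curve()] or any data frame with `vergence_D`
#'   and `vsotf` columns (vergences strictly monotone).
#' @param threshold acceptability criterion (default 0.12, the VSOTF level
#'   associated with acceptable visual acuity).
#' @return list with `interval_D` (c(lower, upper)), `width_D`, `threshold`,
#'   `attained` (FALSE if the peak never reaches threshold, width 0), and
#'   `secondary_lobes` (list of c(lower, upper) intervals).
#' @export
depth_of_focus <- function(curve, threshold = 0.12) {
  stopifnot(all(c("vergence_D", "vsotf") %in% names(curve)),
            nrow(curve) >= 1)
  v <- curve$vergence_D; y <- curve$vsotf
  if (is.unsorted(v, strictly = TRUE)) stop("vergences must be strictly increasing")
  ipk <- which.max(y)
  if (y[ipk] < threshold) {
    return(list(interval_D = c(NA_real_, NA_real_), width_D = 0,
                threshold = threshold, attained = FALSE,
                secondary_lobes = list()))
  }
  above <- y >= threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  lobes <- lapply(which(runs$values), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    lo <- if (i0 == 1) v[1] else {
      # interpolate crossing between i0-1 (below) and i0 (above)
      v[i0 - 1] + (threshold - y[i0 - 1]) / (y[i0] - y[i0 - 1]) * (v[i0] - v[i0 - 1])
    }
    hi <- if (i1 == length(v)) v[length(v)] else {
      v[i1] + (threshold - y[i1]) / (y[i1 + 1] - y[i1]) * (v[i1 + 1] - v[i1])
    }
    c(lo, hi)
  })
  main <- which(vapply(which(runs$values), function(k) {
    ipk >= starts[k] && ipk <= ends[k]
  }, logical(1)))
  interval <- lobes[[main]]
  list(interval_D = interval, width_D = interval[2] - interval[1],
       threshold = threshold, attained = TRUE,
       secondary_lobes = lobes[-main])
}

#' Retinal-illuminance ratio between two pupil diameters
#'
#' Retinal illuminance scales with pupil area, so the ratio between two
#' diameters is (d_to / d_from)^2. The attenuation is also reported in log10
#' units (positive when the pupil shrinks). A constriction from 3.5 mm to
#' 1.5 mm reduces retinal illuminance to ~18% of baseline (~0.74 log units).
#'
#' @param diameter_from_mm,diameter_to_mm positive pupil diameters in mm.
#' @return list with `fraction` (area ratio) and `log10_units`
#'   (-log10(fraction); 0 when the diameters are equal).
#' @export
illuminance_ratio <- function(diameter_from_mm, diameter_to_mm) {
  if (any(diameter_from_mm <= 0) || any(diameter_to_mm <= 0)) {
    stop("pupil diameters must be positive")
  }
  fraction <- (diameter_to_mm / diameter_from_mm)^2
  list(fraction = fraction, log10_units = -log10(fraction))
}
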