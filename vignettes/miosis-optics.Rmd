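---
title: "Modeling through-focus optical quality for pharmacologic miosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling through-focus optical quality for pharmacologic miosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pupilfocus connects two things: a Fourier-optics engine that predicts
through-focus retinal image quality for small-aperture (pharmacologically
constricted) and dual-focus multifocal eye models, and a clinical-synthesis
layer that encodes arm-level pupil data from published miotic presbyopia
trials. The question both address is the same: how small should a drug make
the pupil so that depth of focus improves meaningfully without starving the
retina of light?

## The optical model

An eye model here is a pupil diameter $d$, an optional set of Zernike
aberration coefficients, and an optional zonal lens power profile. The total
wavefront error over the pupil is additive:

$$W(x, y) = \sum_{n,m} c_n^m Z_n^m\!\left(\tfrac{x}{d/2}, \tfrac{y}{d/2}\right) + \frac{V r^2}{2} + \frac{P(r)\, r^2}{2},$$

with $W$ in micrometers, $r$ in millimeters, object vergence $V$ and zone
power $P(r)$ in diopters. Zernike polynomials use the OSA/ANSI double index
with orthonormal normalization (unit mean square over the pupil); the
vergence term projects onto defocus as
$c_2^0 = V (d/2)^2 / (4\sqrt{3})$, and the inverse map recovers $V$ exactly.
Positive vergence means myopic defocus of the retinal image. Coefficients
stated at a larger pupil (spherical aberration is conventionally quoted at
6 mm) are rescaled to the analysis pupil by evaluating the expansion on the
smaller concentric disk and refitting — an exact polynomial operation on the
grid, reproducing the $(d_\text{new}/d_\text{old})^n$ leading-order scaling.

Zone powers are *not* piston-matched at zone boundaries: a center-distance
dual-focus lens has genuinely discrete power zones, and the phase steps at
the boundaries are part of the optics being modeled.

Propagation is standard Fraunhofer: the generalized pupil function
$P = A e^{i 2\pi W/\lambda}$ is zero-padded and Fourier-transformed; the PSF
is $|\mathcal{F}P|^2$ normalized to unit volume, and the OTF is the Fourier
transform of the PSF normalized to 1 at zero frequency. One PSF sample spans
$\lambda/(N\,\Delta x)$ radians; frequencies are reported in cycles/degree
with cutoff $f_c = d/\lambda$ cycles/radian $\times\, \pi/180$. The default
wavelength is 555 nm (photopic luminosity peak); the model is monochromatic.

The pupil is sampled at half-sample-centered coordinates
$x_i = (i - N/2 + \tfrac12)\Delta x$. This makes the sampled aperture exactly
symmetric under point reflection, so pure-defocus PSFs at $\pm V$ are equal
to machine precision, and no lattice point ever sits exactly on the aperture
edge.

## The image-quality metric

Image quality at each vergence is the visual Strehl ratio of the OTF:

$$\mathrm{VSOTF} = \frac{\iint \mathrm{CSF_N}(f)\, |\mathrm{OTF}(f)|\, df}{\iint \mathrm{CSF_N}(f)\, \mathrm{OTF_{DL}}(f)\, df},$$

with the diffraction-limited reference at the *same* pupil diameter, so every
aberration-free condition scores exactly 1 at 0 D and the metric isolates
aberration and defocus effects from pure aperture effects. A fixed-diameter
reference (which materially lowers curves for other pupil sizes) is available
via `reference_diameter_mm`; because a different diameter implies a different
frequency pitch, that reference is evaluated from the analytic
circular-aperture MTF on the test grid.

Two numerator conventions circulate. The signed form weights
$\mathrm{Re}[\mathrm{OTF}]$ and treats phase-reversed (spurious-resolution)
contrast as harmful; it is standard in objective-refraction work. The
frequency-domain form used here by default weights $|\mathrm{OTF}|$ and
counts reversed contrast as usable structure. For the through-focus question
the choice matters: with the modulus form the aberration-free 1.5 mm pupil
holds VSOTF $\ge 0.12$ over about 4.1 D of vergence, consistent with
published small-aperture modeling that reports letter legibility over
sweeps of up to 4.00 D, whereas the signed form crosses the criterion near
$\pm1.5$ D under every CSF weighting we tried. The signed variant remains
available (`numerator = "real"`); switching it only rescales how quickly
curves fall, not any ordering between conditions.

The neural weighting $\mathrm{CSF_N}$ is a radially symmetric parametric
contrast-sensitivity function (Mannos–Sakrison form,
$a(b + cf)\exp(-(cf)^{1.1})$ with $a = 2.6$, $b = 0.0192$, $c = 0.114$),
clamped to zero beyond 60 cycles/degree. The source analyses never state
their CSF parameters; we verified that depth-of-focus widths move by less
than 0.1 D across reasonable alternatives (log-parabola neural CSFs with
peaks at 3 cpd, with or without a flat low-frequency shoulder), because the
two-dimensional frequency integral is dominated by the mid-frequency annulus
under any of them. The parameters travel inside the `neural_csf` object so
every curve records what produced it.

**Depth of focus** is the width of the maximal contiguous vergence interval
containing the global VSOTF peak with VSOTF $\ge 0.12$ — the threshold
associated in the literature with acceptable (roughly 20/32) visual acuity.
Boundaries are refined below the sweep step by linear interpolation between
bracketing samples. Disjoint secondary lobes (the near peak of a multifocal)
are reported separately rather than added to the width, and a curve whose
peak never reaches the threshold reports width 0 with `attained = FALSE`.

## Model presets and their provenance

`naked_eye_{1.5,2.0,2.5,3.0,3.5}mm` are aberration-free apertures. These
diameters span pharmacologically achievable miotic pupils (photopic/mesopic,
roughly 1.5–2.5 mm) and typical untreated indoor adult pupils (3.0–3.5 mm).
The aberration-free default is deliberate: residual higher-order aberrations
of treated eyes are unreported in the trials, and an aberration-free model
isolates the aperture effect. Age-typical spherical aberration can be added
through the `zernike` slot of `eye_model()`.

`dual_focus_{3.0,3.5,4.0,5.0}mm` use a synthetic center-distance design:
central 0.75 mm-radius distance zone, then alternating near/distance annuli
(boundaries at 1.25, 1.75, 2.25, 3.0 mm). The published figure this emulates
does not print the commercial lens's zone radii or add power, so these are
package choices, not a reconstruction. The add power is +1.00 D: under the
additive sign convention a zone of power $P$ focuses objects at vergence
$-P$, which places the near VSOTF peak near $-1$ D for a 5 mm pupil, where
the source figure shows it. Results for the dual-focus rows should be read
as "a representative concentric dual-focus design", and the acceptance
checks accordingly assert only that its acceptable zone is materially
narrower than the 1.5 mm aperture's, reporting its exact width rather than
pinning it.

## Numerical choices

* Default grid: 256 samples across the pupil, padding factor 4 (1024²
  transforms). VSOTF at this grid agrees with a doubled grid to better than
  $10^{-3}$; the Airy zero, the analytic circular-aperture MTF, and a direct
  DFT oracle validate the propagation. Property tests run at 128/2, which is
  ~50× faster and still accurate to ~$10^{-3}$.
* Through-focus sweeps default to 0.05 D steps over ±4 D; analysis tables in
  `results/` record the step used. Interval endpoints are linearly
  interpolated, so the step mainly limits lobe detection, not boundary
  precision.
* `compute_psf()` refuses pupils sampled with fewer than 64 points across
  the diameter; `render_snellen_e()` refuses fewer than 5 samples per
  stroke. Degenerate depth-of-focus inputs (flat curves, subthreshold
  curves) are defined outcomes, not errors.
* Optotype convolution is linear (zero-padded FFT) on ink intensity
  $1 - \text{pixels}$ with a unit-sum kernel, so total ink flux is conserved
  exactly and contrast can only shrink. When a PSF must be resampled to the
  letter grid, interpolation is bilinear followed by renormalization; panel
  cells truncate the kernel to the cell extent, with the discarded tail mass
  (≲$10^{-4}$) reabsorbed by renormalization.

## The clinical synthesis

`study_table()` ships one row per treatment arm of the published pilocarpine
(1.25%, 0.4%, 0.2%, and other formulations), carbachol, and phentolamine
presbyopia studies: baseline and post-treatment pupil diameter, dosing,
lighting, timing, evidence level, and whether values were digitized from
figures. Multi-stratum reports are split into separate arms: per-study-day
concentrations are keyed by concentration (they are aggregated that way in
the narrative synthesis), and age strata are separate arms.

The derived quantities are deliberately simple, mirroring the published
narrative synthesis rather than a formal meta-analysis: per-arm deltas
(baseline − post, half-up rounding at 2 decimals, missing data flagged and
never imputed), min–max ranges per formulation over active arms only, and
the inclusive 0.90 mm threshold for clinically meaningful constriction (the
minimum-effective 0.4% pilocarpine arm sits exactly at 0.90). Two known
wrinkles are handled explicitly rather than forced to match prose: the 0.4%
delta range recomputes to 0.90–1.06 mm (the published upper bound of 1.10 is
not derivable from the printed arm values), and the published carbachol
net-reduction range (2.11–3.10 mm) requires excluding the
carbachol-without-brimonidine arm, so that exclusion is the default and the
rule is configurable.

The age–luminance regressions are linear senile-miosis models: pupil
diameter $= 2.57 - 0.008\,\text{age}$ mm under bright outdoor light
(>1000 lux melanopic EDI) and $4.32 - 0.020\,\text{age}$ mm under indoor
light (10–100 lux melanopic EDI). `crosswalk_report()` then places each
arm's achieved pupil onto the modeled diameter grid and tests membership in
the 2.0–2.5 mm band that balances depth of focus against retinal
illuminance; `illuminance_ratio()` supplies the area-law attenuation
(3.5 → 1.5 mm keeps ~18% of retinal illuminance, ~0.74 log units).

## What the synthetic generator does and does not emulate

`simulate_trial_table()` reproduces the *structure* of the arm-level table:
baselines $\sim N(3.2, 0.3^2)$ mm truncated to (1, 9), active constriction
effects drawn per formulation from truncated normals (miosis cannot be a
dilation under these agents — a modeling choice), vehicle changes
$\sim N(0, 0.05^2)$, lighting mixed photopic/mesopic/scotopic, and ~10%
missing pupil data. One seed drives one RNG stream with draws in fixed
column order, so tables are bit-reproducible. It does **not** emulate
within-arm subject variance feeding into reported means, correlated
baselines within studies, dropout, or visual-acuity outcomes — so passing
parameter-recovery tests shows the synthesis arithmetic is correct, not that
the generator is a realistic trial simulator.

## Known limitations

Monochromatic optics only; no Stiles–Crawford apodization, scatter, or
photon-noise modeling — in dim light those mechanisms penalize very small
pupils beyond what these curves show, which is exactly why the clinical
band of interest stops near 2.0 mm rather than extending to the optical
optimum. The dual-focus preset is representative, not a commercial design.
The neural CSF is luminance-independent; mesopic/scotopic contrast
sensitivity switching is out of scope.
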