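# Pupil function, PSF propagation, OTF scaling

test_that("pupil function is the disk indicator for a flat wavefront", {
  wf <- compose_wavefront(pupil_diameter_mm = 2, n_samples = 64)
  P <- build_pupil_function(wf, 555)
  g <- pupil_grid(2, 64)
  expect_true(all(P[g$mask] == 1 + 0i))
  expect_true(all(P[!g$mask] == 0 + 0i))
})

test_that("one full wave of OPD wraps to the same pupil function", {
  wf0 <- compose_wavefront(pupil_diameter_mm = 2, n_samples = 64)
  wf1 <- wf0
  wf1$phase_error_um <- wf0$phase_error_um + 0.555  # exactly one wave at 555 nm
  P0 <- build_pupil_function(wf0, 555)
  P1 <- build_pupil_function(wf1, 555)
  expect_equal(P1, P0, tolerance = 1e-12)
})

test_that("defocus phase peaks at the analytic pupil-edge value", {
  d <- 3; c20 <- 0.25
  v <- defocus_coefficient_to_vergence(c20, d)
  wf <- compose_wavefront(vergence_D = v, pupil_diameter_mm = d,
                          n_samples = 512)
  lambda_um <- 0.555
  # W = V r^2/2 spans [0, 2 sqrt(3) c20]; peak phase 2 pi (2 sqrt(3) c20)/lambda,
  # equivalently the peak-to-valley of the c20 Z(2,0) term
  expect_equal(max(wf$phase_error_um, na.rm = TRUE) * 2 * pi / lambda_um,
               2 * pi * (2 * sqrt(3) * c20) / lambda_um, tolerance = 1e-2)
})

test_that("PSFs are non-negative, unit-sum, and demand adequate sampling", {
  m <- preset_eye_model("naked_eye_2.5mm")
  for (v in c(0, 1.5)) {
    wf <- compose_wavefront(vergence_D = v, pupil_diameter_mm = 2.5,
                            n_samples = 128)
    p <- compute_psf(build_pupil_function(wf), padding_factor = 2)
    expect_true(all(p$intensity >= 0))
    expect_equal(sum(p$intensity), 1, tolerance = 1e-12)
  }
  wf <- compose_wavefront(pupil_diameter_mm = 2, n_samples = 32)
  expect_error(compute_psf(build_pupil_function(wf)), "coarse")
  wf <- compose_wavefront(pupil_diameter_mm = 2, n_samples = 64)
  expect_error(compute_psf(build_pupil_function(wf), padding_factor = 1), ">= 2")
})

test_that("diffraction-limited first Airy zero sits at 1.22 lambda/D", {
  wf <- compose_wavefront(pupil_diameter_mm = 2, n_samples = 128)
  p <- compute_psf(build_pupil_function(wf, 555), padding_factor = 4)
  N <- nrow(p$intensity); c0 <- N %/% 2 + 1
  profile <- p$intensity[c0, c0:N]
  first_min <- which(diff(profile) > 0)[1]  # first rising step = past the zero
  r_zero_arcmin <- (first_min - 1) * p$sample_scale_arcmin
  analytic <- 1.22 * 555e-9 / 2e-3 * 180 / pi * 60
  expect_equal(analytic, 1.164, tolerance = 1e-3)
  expect_lt(abs(r_zero_arcmin - analytic), p$sample_scale_arcmin)
})

test_that("FFT propagation matches a direct DFT oracle on a 64^2 pupil", {
  wf <- compose_wavefront(vergence_D = 0.8, pupil_diameter_mm = 2,
                          n_samples = 64)
  P <- build_pupil_function(wf, 555)
  p <- compute_psf(P, padding_factor = 2)
  # oracle: explicit DFT matrix applied to the same zero-padded array
  N <- 128
  big <- matrix(0 + 0i, N, N)
  big[33:96, 33:96] <- P
  Fm <- exp(-2i * pi * outer(0:(N - 1), 0:(N - 1)) / N)
  field <- Fm %*% big %*% Fm
  oracle <- Mod(field)^2
  oracle <- oracle / sum(oracle)
  # same fftshift layout as compute_psf
  oracle <- oracle[c(65:128, 1:64), c(65:128, 1:64)]
  expect_lt(max(abs(oracle - p$intensity)), 1e-10)
})

test_that("OTF of a delta PSF is identically 1", {
  k <- matrix(0, 64, 64); k[33, 33] <- 1
  o <- compute_otf(manual_psf(k, 0.25))
  expect_lt(max(Mod(o$values - 1)), 1e-12)
})

test_that("diffraction-limited OTF matches the circular-aperture closed form", {
  wf <- compose_wavefront(pupil_diameter_mm = 2, n_samples = 128)
  o <- compute_otf(compute_psf(build_pupil_function(wf, 555), 2))
  fr <- otf_frequencies(o)
  N <- nrow(o$values); c0 <- N %/% 2 + 1
  sel <- cbind(c0, seq(c0, N, by = 3))  # radial cut along +fx
  expect_lt(max(abs(Mod(o$values[sel]) -
                      diffraction_limited_mtf(fr$fr[sel], 2, 555))), 1e-2)
  # cutoff frequency D/lambda in cycles/radian, scaled to cycles/degree
  fc <- 2e-3 / 555e-9 * pi / 180
  expect_gt(fc, 62); expect_lt(fc, 64)
  expect_lt(max(Mod(o$values[fr$fr > fc * 1.02])), 1e-9)
})

test_that("real PSFs give Hermitian OTFs with modulus bounded by the DL MTF", {
  m <- eye_model(2.5, zernike = zernike_coefficients(4, 0, 0.3, 2.5))
  o <- fast_otf(m, vergence_D = 0.7)
  N <- nrow(o$values); c0 <- N %/% 2 + 1
  idx <- 2:N
  flipped <- o$values[rev(idx), rev(idx)]
  expect_lt(max(Mod(flipped - Conj(o$values[idx, idx]))), 1e-12)
  expect_lt(max(Mod(o$values)), 1 + 1e-9)
  o_dl <- fast_otf(eye_model(2.5))
  expect_true(all(Mod(o$values) <= Mod(o_dl$values) + 1e-9))
})

test_that("pure-defocus PSFs are exactly even in defocus", {
  for (d in c(1.5, 3)) {
    wp <- compute_psf(build_pupil_function(
      compose_wavefront(vergence_D = 1.3, pupil_diameter_mm = d, n_samples = 128)), 2)
    wm <- compute_psf(build_pupil_function(
      compose_wavefront(vergence_D = -1.3, pupil_diameter_mm = d, n_samples = 128)), 2)
    expect_lt(max(abs(wp$intensity - wm$intensity)), 1e-10)
  }
})

test_that("PSF energy is conserved across the vergence sweep", {
  for (v in c(-2, -0.5, 0.9, 2)) {
    p <- compute_psf(build_pupil_function(
      compose_wavefront(vergence_D = v, pupil_diameter_mm = 3, n_samples = 128)), 2)
    expect_equal(sum(p$intensity), 1, tolerance = 1e-12)
  }
})
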