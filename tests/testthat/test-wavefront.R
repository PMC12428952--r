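# Zernike basis, defocus conversion, power profiles, wavefront composition

test_that("Zernike basis has the analytic values and rejects invalid indices", {
  g <- pupil_grid(2, 64)
  xn <- g$x; yn <- g$y  # pupil radius 1, so coords are already normalized
  z00 <- evaluate_zernike_basis(0, 0, xn, yn)
  expect_true(all(z00[g$mask] == 1))
  expect_true(all(z00[!g$mask] == 0))
  # Z(2,0) = sqrt(3) (2 rho^2 - 1): edge value sqrt(3), center -sqrt(3)
  expect_equal(evaluate_zernike_basis(2, 0, 1, 0), sqrt(3) * (2 - 1))
  expect_equal(evaluate_zernike_basis(2, 0, 0, 0), -sqrt(3))
  expect_error(evaluate_zernike_basis(2, 1, xn, yn), "invalid")
  expect_error(evaluate_zernike_basis(3, -2, xn, yn), "invalid")
  expect_error(zernike_coefficients(2, 3, 0.1, 3), "invalid")
})

test_that("Zernike basis is discretely orthonormal on a 512^2 grid", {
  g <- pupil_grid(2, 512)
  xn <- g$x; yn <- g$y
  w <- g$mask / sum(g$mask)  # normalized disk quadrature weights
  pairs <- list(c(2, 0), c(4, 0), c(2, -2), c(3, 1))
  fields <- lapply(pairs, function(p) evaluate_zernike_basis(p[1], p[2], xn, yn))
  for (i in seq_along(pairs)) {
    expect_equal(sum(w * fields[[i]]^2), 1, tolerance = 1e-3)
    for (j in seq_along(pairs)) if (j > i) {
      expect_lt(abs(sum(w * fields[[i]] * fields[[j]])), 1e-3)
    }
  }
})

test_that("vergence-to-defocus matches a least-squares projection oracle", {
  # oracle: project W = V r^2 / 2 onto Z(2,0) on a fine disk grid
  g <- pupil_grid(3, 512)
  z20 <- evaluate_zernike_basis(2, 0, g$x / 1.5, g$y / 1.5)
  W <- 1 * (g$x^2 + g$y^2) / 2  # 1 D over a 3 mm pupil, r in mm
  m <- g$mask
  c20_oracle <- sum((W * z20)[m]) / sum((z20^2)[m])
  expect_equal(c20_oracle, 2.25 / (4 * sqrt(3)), tolerance = 1e-4)
  expect_equal(vergence_to_defocus_coefficient(1, 3), 2.25 / (4 * sqrt(3)))
  expect_equal(vergence_to_defocus_coefficient(1, 3), 0.3247595, tolerance = 1e-6)
  # linearity in vergence
  expect_equal(vergence_to_defocus_coefficient(-2, 3), -2 * 0.3247595,
               tolerance = 1e-6)
  expect_equal(vergence_to_defocus_coefficient(0, 5), 0)
  expect_error(vergence_to_defocus_coefficient(1, -3), "positive")
})

test_that("vergence -> c(2,0) -> vergence round trip is exact to 1e-12", {
  for (v in c(-3.7, -1, 0.05, 2.25)) {
    for (d in c(1.5, 3, 6.2)) {
      c20 <- vergence_to_defocus_coefficient(v, d)
      expect_equal(defocus_coefficient_to_vergence(c20, d), v,
                   tolerance = 1e-12)
    }
  }
})

test_that("power profiles validate geometry and map to quadratic phase", {
  expect_error(power_profile(0.5, 1, 2), "radius 0")
  expect_error(power_profile(c(0, 1.2), c(1, 2), c(0, 1)), "contiguous")
  expect_error(power_profile(0, 1, Inf), "finite")

  flat <- power_profile(0, 2, 0)
  wf <- power_profile_to_wavefront(flat, 3, n_samples = 96)
  expect_true(all(wf$phase_error_um[!is.na(wf$phase_error_um)] == 0))

  one_d <- power_profile(0, 1.5, 1)
  fit <- fit_zernike(power_profile_to_wavefront(one_d, 3, 256), max_n = 4)
  expect_equal(zernike_value(fit, 2, 0), 0.3247595, tolerance = 1e-4)

  expect_error(power_profile_to_wavefront(power_profile(0, 1, 1), 3), "covers")
})

test_that("two-zone profile recovers per-zone powers under masked regression", {
  prof <- power_profile(c(0, 0.75), c(0.75, 1.5), c(0, 2.5))
  wf <- power_profile_to_wavefront(prof, 3, n_samples = 256)
  g <- pupil_grid(3, 256)
  r <- sqrt(g$x^2 + g$y^2)
  for (i in 1:2) {
    sel <- g$mask & r >= prof$inner_radius_mm[i] & r < prof$outer_radius_mm[i] &
      !is.na(wf$phase_error_um)
    # phase = P r^2/2 within the zone: regress phase on r^2/2
    p_hat <- sum(wf$phase_error_um[sel] * (r[sel]^2 / 2)) / sum((r[sel]^2 / 2)^2)
    expect_equal(p_hat, prof$power_D[i], tolerance = 1e-10)
  }
})

test_that("compose_wavefront assembles components additively", {
  wf0 <- compose_wavefront(pupil_diameter_mm = 3, n_samples = 96)
  expect_true(all(wf0$phase_error_um[!is.na(wf0$phase_error_um)] == 0))

  wf2 <- compose_wavefront(vergence_D = 2, pupil_diameter_mm = 1.5,
                           n_samples = 256)
  fit <- fit_zernike(wf2, max_n = 4)
  expect_equal(zernike_value(fit, 2, 0), 2 * 0.5625 / (4 * sqrt(3)),
               tolerance = 1e-4)

  # superposition on random components
  set.seed(42)
  z <- zernike_coefficients(c(2, 4, 3), c(0, 0, -1), stats::rnorm(3, 0, 0.3), 3)
  prof <- power_profile(c(0, 0.8), c(0.8, 1.5), c(0, 1.3))
  whole <- compose_wavefront(z, 1.2, prof, 3, n_samples = 96)
  parts <- compose_wavefront(z, 0, NULL, 3, 96)$phase_error_um +
    compose_wavefront(NULL, 1.2, NULL, 3, 96)$phase_error_um +
    compose_wavefront(NULL, 0, prof, 3, 96)$phase_error_um
  expect_equal(whole$phase_error_um, parts, tolerance = 1e-12)
})

test_that("aperture rescaling follows the disk-resampling refit", {
  z <- zernike_coefficients(4, 0, 1.0, pupil_diameter_mm = 6)
  z3 <- rescale_zernike(z, 3, n_samples = 256)
  # leading term scales as (3/6)^4
  expect_equal(zernike_value(z3, 4, 0), 1.0 * 0.5^4, tolerance = 1e-6)
  # the refit also picks up the induced defocus term. Closed form: the disk
  # average of Z(4,0)(rho/2) * Z(2,0)(rho) with <rho^2>=1/2, <rho^4>=1/3,
  # <rho^6>=1/4 gives sqrt(15) * (-0.1875) = -0.72618. Cross-check with a
  # midpoint polar-quadrature oracle, then against the refit.
  th <- (seq_len(720) - 0.5) / 720 * 2 * pi
  rr <- sqrt((seq_len(400) - 0.5) / 400)  # uniform in area
  pts <- expand.grid(r = rr, t = th)
  x <- pts$r * cos(pts$t); y <- pts$r * sin(pts$t)
  w_orig <- evaluate_zernike_basis(4, 0, x / 2, y / 2)  # new radius = half old
  z20 <- evaluate_zernike_basis(2, 0, x, y)
  c20_oracle <- mean(w_orig * z20)  # orthonormal basis, uniform-area sampling
  expect_equal(c20_oracle, sqrt(15) * -0.1875, tolerance = 1e-5)
  expect_equal(zernike_value(z3, 2, 0), c20_oracle, tolerance = 1e-3)
  # equal-diameter rescale is the identity
  expect_identical(rescale_zernike(z, 6), z)
  expect_error(rescale_zernike(z, 7), "smaller")
  # composing a base defined at a smaller pupil than the analysis pupil fails
  z_small <- zernike_coefficients(2, 0, 0.1, pupil_diameter_mm = 2)
  expect_error(compose_wavefront(z_small, 0, NULL, 3, 64), "extrapolated")
})

test_that("model YAML serialization round-trips", {
  tmp <- tempfile(fileext = ".yaml")
  z <- zernike_coefficients(c(2, 4), c(0, 0), c(0.12345678901, -0.5), 6)
  write_model_yaml(z, tmp)
  z2 <- read_model_yaml(tmp)
  expect_equal(z2$value_um, z$value_um, tolerance = 1e-12)
  expect_equal(attr(z2, "pupil_diameter_mm"), 6)

  m <- preset_eye_model("dual_focus_3.0mm")
  write_model_yaml(m, tmp)
  m2 <- read_model_yaml(tmp)
  expect_equal(m2$pupil_diameter_mm, 3)
  expect_equal(m2$profile$power_D, m$profile$power_D)
  unlink(tmp)
})

test_that("presets cover the published model conditions", {
  expect_length(preset_names(), 9)
  for (nm in preset_names()) {
    m <- preset_eye_model(nm)
    expect_s3_class(m, "eye_model")
  }
  expect_null(preset_eye_model("naked_eye_1.5mm")$profile)
  expect_s3_class(preset_eye_model("dual_focus_5.0mm")$profile, "power_profile")
  expect_error(preset_eye_model("naked_eye_9mm"), "preset")
})
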