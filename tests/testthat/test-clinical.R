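# Clinical synthesis: packaged table, deltas, ranges, thresholds, regressions

tab <- study_table()

test_that("the packaged study table satisfies the arm-level invariants", {
  expect_equal(nrow(tab), 33)
  expect_true(all(tab$evidence_level %in% 1:3))
  expect_true(all(tab$n >= 1))
  pupils <- c(tab$baseline_pupil_mm, tab$post_pupil_mm)
  pupils <- pupils[!is.na(pupils)]
  expect_true(all(pupils > 0 & pupils < 10))
  expect_true(all(tab$arm_type %in%
    c("active", "vehicle", "placebo", "nsaid_only", "comparator")))
  expect_true(all(tab$lighting %in%
    c("photopic", "mesopic", "scotopic", "unreported")))
  expect_false(any(duplicated(tab$arm_id)))
})

test_that("constriction deltas reproduce the printed per-arm differences", {
  d <- constriction_delta(tab)
  expect_equal(d$delta_mm[d$arm_id == "pepose_2021_phento"], 0.98)
  expect_equal(d$delta_mm[d$arm_id == "waring_2022_pilo"], 1.54)
  expect_equal(d$delta_mm[d$arm_id == "holland_2024_pilo"], 1.06)
  # missing values are flagged, never silently zero
  miss <- d[d$arm_id == "benozzi_2012", ]
  expect_true(is.na(miss$delta_mm))
  expect_true(miss$delta_missing)
  # equal baseline and post give an honest zero
  fake <- tibble::tibble(baseline_pupil_mm = 3.1, post_pupil_mm = 3.1)
  expect_equal(constriction_delta(fake)$delta_mm, 0)
})

test_that("formulation-level ranges reproduce the published synthesis", {
  r125 <- group_ranges(tab, "1.25% pilocarpine")
  expect_equal(r125$baseline_range, c(2.68, 3.40))
  expect_equal(r125$post_range, c(1.23, 1.97))
  expect_equal(r125$delta_range, c(1.10, 1.54))
  expect_equal(r125$n_arms, 4)
  expect_equal(r125$n_excluded_missing, 2)  # Lievens, Waring 2024: not collected

  r02 <- group_ranges(tab, "0.2% pilocarpine")
  expect_equal(r02$baseline_range, c(3.17, 3.28))
  expect_equal(r02$post_range, c(2.37, 2.46))
  expect_equal(r02$delta_range, c(0.80, 0.82))

  r04 <- group_ranges(tab, "0.4% pilocarpine")
  expect_equal(r04$baseline_range, c(3.02, 3.36))
  expect_equal(r04$post_range, c(2.12, 2.30))
  # recomputed delta range: the printed upper bound (1.10) is not recoverable
  # from the printed arm values; the table yields 0.90-1.06
  expect_equal(r04$delta_range, c(0.90, 1.06))
})

test_that("the carbachol inclusion rule controls the reported range", {
  comb <- group_ranges(tab, "carbachol")
  expect_equal(comb$delta_range, c(2.11, 3.10))
  expect_equal(comb$baseline_range, c(4.30, 4.77))
  expect_equal(comb$post_range, c(1.20, 2.61))
  all_arms <- group_ranges(tab, "carbachol", carbachol_rule = "all_active")
  expect_equal(all_arms$delta_range, c(1.50, 3.10))
})

test_that("single-arm groups give degenerate ranges and empty groups error", {
  ph <- group_ranges(tab, "phentolamine")
  expect_equal(ph$delta_range, c(0.98, 0.98))
  expect_error(group_ranges(tab, "aceclidine"), "no arms")
  expect_error(group_ranges(tab, "benozzi"), "complete pupil data")
})

test_that("figure-extracted arms can be excluded", {
  r <- group_ranges(tab, "1.25% pilocarpine", include_figure_extracted = FALSE)
  expect_equal(r$n_arms, 2)  # only the directly measured arms remain
  expect_equal(r$baseline_range, c(2.68, 2.78))
})

test_that("the 0.90 mm meaningful-constriction threshold is inclusive", {
  expect_true(meets_meaningful_constriction(0.90))
  expect_false(meets_meaningful_constriction(0.82))
  expect_false(meets_meaningful_constriction(0))
  expect_equal(meets_meaningful_constriction(c(1.54, 0.8, NA)),
               c(TRUE, FALSE, NA))
})

test_that("age-luminance regressions reproduce the printed estimates", {
  ages <- seq(40, 65, by = 5)
  expect_equal(predict_pupil(ages, pupil_age_model("bright")),
               c(2.25, 2.21, 2.17, 2.13, 2.09, 2.05))
  expect_equal(predict_pupil(ages, pupil_age_model("indoor")),
               c(3.52, 3.42, 3.32, 3.22, 3.12, 3.02))
  expect_warning(p0 <- predict_pupil(0, pupil_age_model("bright")), "18-90")
  expect_equal(p0, 2.57)  # the intercept
  m <- pupil_age_model("indoor")
  expect_lte(m$slope_mm_per_year, 0)
  expect_gt(m$intercept_mm, 0)
})

test_that("the crosswalk maps achieved pupils onto the model grid", {
  dof <- data.frame(pupil_diameter_mm = c(1.5, 2.0, 2.5, 3.0, 3.5),
                    width_D = c(4.1, 2.6, 2.0, 1.5, 1.3))
  cw <- crosswalk_report(tab, dof)
  arms <- cw$arms
  holland <- arms[arms$arm_id == "holland_2024_pilo", ]
  expect_equal(holland$nearest_model_mm, 2.5)  # post 2.30 mm
  expect_true(holland$in_band)
  mousavi <- arms[arms$arm_id == "mousavi_2024_generic", ]
  expect_false(mousavi$in_band)  # post 1.23 mm, below 2.0
  expect_equal(cw$n_excluded_missing,
               sum(tab$arm_type == "active" & is.na(tab$post_pupil_mm)))
  expect_true(all(arms$modeled_dof_D %in% dof$width_D))
  expect_gte(cw$fraction_in_band, 0)
  expect_lte(cw$fraction_in_band, 1)
})
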