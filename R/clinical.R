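#' @title Clinical synthesis of miotic presbyopia trials
#' @description Arm-level encoding of published pilocarpine, carbachol and
#'   phentolamine presbyopia trials, pupil-constriction arithmetic,
#'   formulation-level min-max ranges, the 0.90 mm clinical-meaningfulness
#'   threshold, age-luminance pupil regressions, and the crosswalk between
#'   clinically achieved pupil sizes and modeled depth of focus.
#' @name clinical_synthesis
NULL

# round half away from zero at k decimals (base round() is round-half-even;
# clinical deltas are reported with conventional half-up rounding)
round_half_up <- function(x, k = 2) sign(x) * floor(abs(x) * 10^k + 0.5) / 10^k

#' Packaged arm-level study table
#'
#' One row per treatment arm of the published miotic presbyopia studies:
#' drug, concentration, dosing, sample size, baseline and post-treatment
#' pupil diameter (mm; NA where a study did not collect or report pupil
#' size), statistical significance, time after instillation, lighting
#' condition, evidence level (1 = high-quality RCT, 2 = well-designed
#' non-randomized/cohort/case-control, 3 = case series or expert opinion),
#' and whether the pupil values were extracted from a published figure
#' rather than reported numerically. Multi-stratum reports are split into
#' separate arms (per-concentration study days; age strata).
#'
#' @return a tibble, one row per arm.
#' @export
study_table <- function() {
  path <- system.file("extdata", "pilocarpine_pupil_table.csv",
                      package = "pupilfocus", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  tibble::as_tibble(tab)
}

#' Per-arm pupil-constriction delta
#'
#' delta = baseline - post-treatment pupil diameter. Arms missing either
#' value get NA (flagged in `delta_missing`), never a silent zero. The
#' reported value is rounded half-up to 2 decimals; the raw difference is
#' kept in `delta_raw_mm`.
#'
#' @param table an arm-level table as from [study_table()].
#' @return the table with columns `delta_raw_mm`, `delta_mm` (rounded),
#'   `delta_missing` appended.
#' @export
constriction_delta <- function(table) {
  stopifnot(all(c("baseline_pupil_mm", "post_pupil_mm") %in% names(table)))
  raw <- table$baseline_pupil_mm - table$post_pupil_mm
  dplyr::mutate(table,
                delta_raw_mm = raw,
                delta_mm = round_half_up(raw, 2),
                delta_missing = is.na(raw))
}

#' Formulation-level min-max ranges
#'
#' Computes (min, max) of mean baseline pupil, mean post-treatment pupil, and
#' constriction delta over the active arms of one formulation group.
#' Vehicle/placebo/NSAID-only/comparator arms are never part of a
#' formulation group; arms without pupil data are excluded and counted.
#'
#' For the carbachol group the published synthesis range is reproducible only
#' when the carbachol-without-brimonidine arm is excluded; the default rule
#' `"combination_only"` does so, `"all_active"` keeps it.
#'
#' @param table an arm-level table (see [study_table()]).
#' @param group label in the table's `formulation_group` column, e.g.
#'   `"1.25% pilocarpine"`.
#' @param include_figure_extracted keep arms whose pupil values were
#'   digitized from figures (default TRUE, as in the published synthesis).
#' @param carbachol_rule `"combination_only"` (default) or `"all_active"`.
#' @return list with `baseline_range`, `post_range`, `delta_range` (each
#'   c(min, max), 2-decimal), `n_arms` used, and `n_excluded_missing`.
#' @export
group_ranges <- function(table, group, include_figure_extracted = TRUE,
                         carbachol_rule = c("combination_only", "all_active")) {
  carbachol_rule <- match.arg(carbachol_rule)
  arms <- dplyr::filter(table, .data$arm_type == "active",
                        !is.na(.data$formulation_group),
                        .data$formulation_group == group)
  if (!include_figure_extracted) {
    arms <- dplyr::filter(arms, .data$figure_extracted != "yes")
  }
  if (group == "carbachol" && carbachol_rule == "combination_only") {
    # drop carbachol-without-brimonidine arms; leaves non-carbachol drugs
    # (e.g. simulated tables reusing the label) untouched
    arms <- dplyr::filter(arms, .data$drug != "carbachol" | !is.na(.data$co_drug))
  }
  if (nrow(arms) == 0) stop(sprintf("no arms in group '%s' after exclusions", group))
  complete <- !is.na(arms$baseline_pupil_mm) & !is.na(arms$post_pupil_mm)
  n_excluded <- sum(!complete)
  arms <- arms[complete, ]
  if (nrow(arms) == 0) {
    stop(sprintf("group '%s' has no arms with complete pupil data", group))
  }
  arms <- constriction_delta(arms)
  rng <- function(x) round_half_up(c(min(x), max(x)), 2)
  list(baseline_range = rng(arms$baseline_pupil_mm),
       post_range = rng(arms$post_pupil_mm),
       delta_range = rng(arms$delta_mm),
       n_arms = nrow(arms),
       n_excluded_missing = n_excluded)
}

#' Clinically meaningful constriction test
#'
#' A miotic agent must constrict the pupil by at least 0.90 mm to yield a
#' clinically meaningful (>= 3-line / 15-letter) near visual-acuity
#' improvement; the threshold is inclusive (0.90 itself passes — the minimum
#' effective 0.4% pilocarpine arm defines it).
#'
#' @param delta_mm constriction delta(s) in mm (NA propagates).
#' @param threshold_mm meaningfulness threshold (default 0.90).
#' @return logical vector.
#' @export
meets_meaningful_constriction <- function(delta_mm, threshold_mm = 0.90) {
  delta_mm >= threshold_mm
}

#' Age-luminance pupil regression models
#'
#' Linear pupil-diameter-vs-age regressions for natural viewing environments:
#' under bright outdoor light (>1000 lux melanopic EDI) pupil diameter falls
#' by about 0.008 mm/year from an intercept of 2.57 mm; under indoor light
#' (~10-100 lux melanopic EDI) the slope steepens to -0.020 mm/year with an
#' intercept of 4.32 mm (senile miosis is stronger at lower luminance).
#'
#' @param band `"bright"` or `"indoor"`.
#' @return object of class `pupil_age_model`: list with `luminance_band`,
#'   `slope_mm_per_year`, `intercept_mm`.
#' @export
pupil_age_model <- function(band = c("bright", "indoor")) {
  band <- match.arg(band)
  p <- switch(band,
              bright = list(slope = -0.008, intercept = 2.57),
              indoor = list(slope = -0.020, intercept = 4.32))
  structure(list(luminance_band = band,
                 slope_mm_per_year = p$slope,
                 intercept_mm = p$intercept),
            class = "pupil_age_model")
}

#' Predict pupil diameter from age
#'
#' intercept + slope * age, reported to 2 decimals. Ages outside 18-90 years
#' are outside the regressions' support and trigger a warning.
#'
#' @param age_years age(s) in years.
#' @param model a [pupil_age_model()].
#' @return predicted pupil diameter(s) in mm (2-decimal).
#' @examples
#' predict_pupil(40, pupil_age_model("bright"))   # 2.25
#' predict_pupil(65, pupil_age_model("indoor"))   # 3.02
#' @export
predict_pupil <- function(age_years, model = pupil_age_model("bright")) {
  stopifnot(inherits(model, "pupil_age_model"))
  if (any(age_years < 18 | age_years > 90, na.rm = TRUE)) {
    warning("age outside 18-90 years: extrapolating beyond the regression support")
  }
  round_half_up(model$intercept_mm + model$slope_mm_per_year * age_years, 2)
}

#' Crosswalk between clinical pupil sizes and modeled depth of focus
#'
#' For each active arm with a post-treatment pupil measurement, finds the
#' nearest modeled pupil diameter, attaches that model's depth-of-focus
#' width, and tests whether the achieved pupil falls inside the functional
#' band (default 2.0-2.5 mm, the range identified as balancing depth of
#' focus against retinal illuminance).
#'
#' @param table arm-level table (see [study_table()]).
#' @param dof_table data frame with columns `pupil_diameter_mm` and
#'   `width_D` (modeled depth of focus per diameter).
#' @param band length-2 numeric: inclusive functional pupil band in mm.
#' @return list with `arms` (tibble: arm_id, post pupil, nearest modeled
#'   diameter, modeled depth of focus, in_band), `fraction_in_band`, and
#'   `n_excluded_missing` (active arms without a post-treatment pupil).
#' @export
crosswalk_report <- function(table, dof_table, band = c(2.0, 2.5)) {
  stopifnot(all(c("pupil_diameter_mm", "width_D") %in% names(dof_table)))
  active <- dplyr::filter(table, .data$arm_type == "active")
  missing <- is.na(active$post_pupil_mm)
  arms <- active[!missing, ]
  nearest <- vapply(arms$post_pupil_mm, function(p) {
    dof_table$pupil_diameter_mm[which.min(abs(dof_table$pupil_diameter_mm - p))]
  }, numeric(1))
  dof <- dof_table$width_D[match(nearest, dof_table$pupil_diameter_mm)]
  out <- tibble::tibble(
    arm_id = arms$arm_id,
    post_pupil_mm = arms$post_pupil_mm,
    nearest_model_mm = nearest,
    modeled_dof_D = dof,
    in_band = arms$post_pupil_mm >= band[1] & arms$post_pupil_mm <= band[2])
  list(arms = out,
       fraction_in_band = mean(out$in_band),
       n_excluded_missing = sum(missing))
}
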