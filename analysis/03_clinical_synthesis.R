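#!/usr/bin/env Rscript
# Clinical synthesis over the packaged arm-level miotic-presbyopia table:
# per-arm constriction deltas and the 0.90 mm meaningfulness test,
# formulation-level min-max ranges, age-luminance pupil predictions,
# retinal-illuminance trade-offs, and the crosswalk from clinically achieved
# pupils to the modeled depth of focus.

suppressPackageStartupMessages({
  library(pupilfocus)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)
tab <- study_table()

## per-arm deltas -----------------------------------------------------------
deltas <- constriction_delta(tab) |>
  mutate(meaningful = meets_meaningful_constriction(delta_mm)) |>
  select(arm_id, study, year, arm_type, formulation_group,
         baseline_pupil_mm, post_pupil_mm, delta_mm, delta_missing, meaningful)
write.csv(deltas, "results/clinical_arm_deltas.csv", row.names = FALSE)
message(sprintf("%d arms; %d with complete pupil data; %d active arms meet the 0.90 mm threshold",
                nrow(deltas), sum(!deltas$delta_missing),
                sum(deltas$meaningful & deltas$arm_type == "active", na.rm = TRUE)))

## formulation-level ranges -------------------------------------------------
groups <- c("1.25% pilocarpine", "0.4% pilocarpine", "0.2% pilocarpine",
            "carbachol", "phentolamine")
ranges <- bind_rows(lapply(groups, function(g) {
  r <- group_ranges(tab, g)
  tibble::tibble(group = g,
                 baseline_lo = r$baseline_range[1], baseline_hi = r$baseline_range[2],
                 post_lo = r$post_range[1], post_hi = r$post_range[2],
                 delta_lo = r$delta_range[1], delta_hi = r$delta_range[2],
                 n_arms = r$n_arms, n_excluded_missing = r$n_excluded_missing)
}))
write.csv(ranges, "results/clinical_group_ranges.csv", row.names = FALSE)
message("formulation-level ranges (active arms):")
print(as.data.frame(ranges))
# the carbachol rule matters: all-active includes the carbachol-alone arm
r_all <- group_ranges(tab, "carbachol", carbachol_rule = "all_active")
message(sprintf("carbachol deltas: combination-only %.2f-%.2f vs all-active %.2f-%.2f",
                ranges$delta_lo[ranges$group == "carbachol"],
                ranges$delta_hi[ranges$group == "carbachol"],
                r_all$delta_range[1], r_all$delta_range[2]))

## age-luminance pupil predictions ------------------------------------------
ages <- seq(40, 65, by = 5)
preds <- tibble::tibble(
  age_years = ages,
  bright_mm = predict_pupil(ages, pupil_age_model("bright")),
  indoor_mm = predict_pupil(ages, pupil_age_model("indoor")))
write.csv(preds, "results/pupil_age_predictions.csv", row.names = FALSE)
message("age-luminance pupil predictions (mm):")
print(as.data.frame(preds))

## retinal illuminance trade-off --------------------------------------------
illum <- bind_rows(lapply(c(1.5, 2.0, 2.5), function(to) {
  r <- illuminance_ratio(3.5, to)
  tibble::tibble(from_mm = 3.5, to_mm = to,
                 fraction = r$fraction, log10_units = r$log10_units)
}))
write.csv(illum, "results/illuminance_tradeoff.csv", row.names = FALSE)
message(sprintf("3.5 -> 1.5 mm keeps %.1f%% of retinal illuminance (%.2f log units)",
                100 * illum$fraction[1], illum$log10_units[1]))

## crosswalk to the modeled depth of focus ----------------------------------
dof_path <- "results/depth_of_focus.csv"
if (file.exists(dof_path)) {
  dof <- read.csv(dof_path) |>
    filter(grepl("small aperture", condition)) |>
    select(pupil_diameter_mm, width_D)
} else {
  message("depth-of-focus table not found; computing a fast-grid version")
  dof <- bind_rows(lapply(c(1.5, 2, 2.5, 3, 3.5), function(d) {
    cv <- through_focus_curve(eye_model(d), c(-4, 4), step_D = 0.1,
                              pupil_samples = 128, padding_factor = 2)
    tibble::tibble(pupil_diameter_mm = d,
                   width_D = depth_of_focus(cv, 0.12)$width_D)
  }))
}
cw <- crosswalk_report(tab, dof, band = c(2.0, 2.5))
write.csv(cw$arms, "results/clinical_optical_crosswalk.csv", row.names = FALSE)
message(sprintf("%.0f%% of active arms with pupil data land in the 2.0-2.5 mm functional band (%d lacked data)",
                100 * cw$fraction_in_band, cw$n_excluded_missing))
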