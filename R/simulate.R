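#' @title Synthetic trial tables and optical condition sets
#' @name synthetic_data
NULL

# inverse-CDF draw from Normal(mean, sd) truncated below at `lower`
rtruncnorm_lower <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Configuration for the synthetic trial-table generator
#'
#' Defaults emulate the structure of the packaged study table: mean baseline
#' pupils near 3.2 mm with ~0.3 mm between-arm spread, formulation effects
#' spanning ~0.8 mm (0.2% pilocarpine) to ~2.5 mm (carbachol combinations),
#' vehicle arms with near-zero change, a mix of lighting conditions, and
#' occasional studies that did not collect pupil size.
#'
#' @param n_studies number of studies.
#' @param arms_per_study arms per study (the first arm of each study is the
#'   active arm; one additional vehicle arm is generated when
#'   `arms_per_study >= 2`, further arms cycle through the formulations).
#' @param baseline_mean_mm,baseline_sd_mm between-arm baseline distribution;
#'   baselines are truncated to (1, 9) mm.
#' @param formulations data frame with columns `label`, `effect_mean_mm`,
#'   `effect_sd_mm`: the constriction effect per formulation.
#' @param measurement_noise_sd_mm SD of the vehicle-arm pupil change.
#' @param missingness_rate probability an arm's pupil fields are missing.
#' @param lighting_probs named probabilities for photopic/mesopic/scotopic.
#' @return object of class `trial_sim_config`.
#' @export
trial_sim_config <- function(n_studies = 20,
                             arms_per_study = 2,
                             baseline_mean_mm = 3.2,
                             baseline_sd_mm = 0.3,
                             formulations = data.frame(
                               label = c("1.25% pilocarpine", "0.4% pilocarpine",
                                         "0.2% pilocarpine", "carbachol"),
                               effect_mean_mm = c(1.30, 0.95, 0.81, 2.50),
                               effect_sd_mm = c(0.18, 0.08, 0.05, 0.40)),
                             measurement_noise_sd_mm = 0.05,
                             missingness_rate = 0.10,
                             lighting_probs = c(photopic = 0.5, mesopic = 0.3,
                                                scotopic = 0.2)) {
  stopifnot(n_studies >= 1, arms_per_study >= 1,
            baseline_sd_mm >= 0, measurement_noise_sd_mm >= 0,
            all(formulations$effect_sd_mm >= 0),
            missingness_rate >= 0, missingness_rate <= 1,
            all(lighting_probs >= 0), sum(lighting_probs) > 0,
            all(c("label", "effect_mean_mm", "effect_sd_mm") %in%
                  names(formulations)))
  structure(list(n_studies = n_studies, arms_per_study = arms_per_study,
                 baseline_mean_mm = baseline_mean_mm,
                 baseline_sd_mm = baseline_sd_mm,
                 formulations = formulations,
                 measurement_noise_sd_mm = measurement_noise_sd_mm,
                 missingness_rate = missingness_rate,
                 lighting_probs = lighting_probs / sum(lighting_probs)),
            class = "trial_sim_config")
}

#' Simulate an arm-level trial table
#'
#' Generates a table with the same schema as [study_table()]. Active arms
#' draw a constriction delta from Normal(effect_mean, effect_sd) truncated
#' below at 0 (miosis cannot be a dilation under these agents — a modeling
#' choice); vehicle arms draw their delta from
#' Normal(0, measurement_noise_sd). Post-treatment pupil = baseline - delta;
#' baselines are truncated to (1, 9) mm. Missingness is applied to the pupil
#' fields. All randomness comes from one RNG stream seeded once with `seed`
#' (draws in fixed column order), so output is bit-reproducible.
#'
#' @param config a [trial_sim_config()].
#' @param seed integer seed.
#' @return a tibble with the [study_table()] schema plus `true_effect_mm`.
#' @export
simulate_trial_table <- function(config = trial_sim_config(), seed = 1) {
  stopifnot(inherits(config, "trial_sim_config"))
  set.seed(seed)
  forms <- config$formulations
  rows <- vector("list", config$n_studies * config$arms_per_study)
  k <- 0L
  for (s in seq_len(config$n_studies)) {
    form <- forms[((s - 1L) %% nrow(forms)) + 1L, ]
    for (a in seq_len(config$arms_per_study)) {
      k <- k + 1L
      is_vehicle <- config$arms_per_study >= 2 && a == 2L
      baseline <- rtruncnorm_lower(1, config$baseline_mean_mm,
                                   config$baseline_sd_mm, lower = 1)
      baseline <- min(baseline, 9 - 1e-6)
      delta <- if (is_vehicle) {
        stats::rnorm(1, 0, config$measurement_noise_sd_mm)
      } else {
        rtruncnorm_lower(1, form$effect_mean_mm, form$effect_sd_mm, lower = 0)
      }
      missing <- stats::runif(1) < config$missingness_rate
      lighting <- sample(names(config$lighting_probs), 1,
                         prob = config$lighting_probs)
      n_subj <- max(10L, stats::rpois(1, 80))
      rows[[k]] <- tibble::tibble(
        arm_id = sprintf("sim_s%03d_a%d", s, a),
        study = sprintf("SimStudy%03d", s),
        year = 2024L,
        drug = if (is_vehicle) "vehicle" else "simulated miotic",
        concentration_pct = NA_real_,
        co_drug = NA_character_,
        dosing = "QD",
        n = n_subj,
        baseline_pupil_mm = if (missing) NA_real_ else round(baseline, 2),
        baseline_sd_mm = NA_real_,
        post_pupil_mm = if (missing) NA_real_ else round(baseline - delta, 2),
        post_sd_mm = NA_real_,
        significant = NA_character_,
        post_drop_hours_min = 1, post_drop_hours_max = 1,
        lighting = lighting,
        evidence_level = 2L,
        figure_extracted = "no",
        arm_type = if (is_vehicle) "vehicle" else "active",
        formulation_group = if (is_vehicle) NA_character_ else form$label,
        true_effect_mm = if (is_vehicle) 0 else delta)
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a set of optical model configurations
#'
#' Draws random aberration/pupil configurations for property-based optics
#' tests: pupil diameters uniform on `pupil_range_mm` and primary spherical
#' aberration c(4,0) uniform on `sa_range_um` (defined at a 6 mm pupil, the
#' convention for reporting spherical-aberration magnitudes). Reproducible
#' given `seed`.
#'
#' @param n number of configurations.
#' @param sa_range_um length-2 range for c(4,0) in micrometers.
#' @param pupil_range_mm length-2 range for pupil diameter in mm.
#' @param seed integer seed.
#' @return list of [eye_model()] objects (empty list for n = 0).
#' @export
simulate_condition_set <- function(n, sa_range_um = c(-1.5, 1.5),
                                   pupil_range_mm = c(1.5, 5.0), seed = 1) {
  stopifnot(n >= 0, all(is.finite(sa_range_um)), all(is.finite(pupil_range_mm)),
            all(pupil_range_mm > 0))
  if (n == 0) return(list())
  set.seed(seed)
  diam <- stats::runif(n, pupil_range_mm[1], pupil_range_mm[2])
  sa <- stats::runif(n, sa_range_um[1], sa_range_um[2])
  lapply(seq_len(n), function(i) {
    z <- if (sa[i] == 0) NULL else
      zernike_coefficients(4, 0, sa[i], pupil_diameter_mm = 6)
    eye_model(diam[i], zernike = z,
              label = sprintf("sim %.2f mm, c(4,0)=%.2f um", diam[i], sa[i]))
  })
}
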