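# Literature-informed reference values for a sarcopenic cohort of older
# women (n = 26): per-variable marginal means and standard deviations and
# the published imaging-vs-clinical correlation structure. These drive
# the default synthetic cohorts.

#' Reference marginal distributions of the clinical and imaging variables
#'
#' Per-variable mean and standard deviation for a community-dwelling
#' sarcopenic cohort of women aged 70+ — cineanthropometric, functional
#' and respiratory blocks plus the eight imaging biomarkers. Lower bounds
#' mark physical non-negativity used to truncate the Gaussian sampler.
#'
#' @return Tibble with columns `variable`, `block`, `mean`, `sd`, `lower`.
#' @export
ref_marginals <- function() {
  tribble_rows <- list(
    # variable, block, mean, sd, lower
    list("age_years", "cineanthropometric", 81, 8, 0),
    list("weight_kg", "cineanthropometric", 62.7, 11.7, 0),
    list("height_m", "cineanthropometric", 1.50, 0.05, 0),
    list("bmi_kg_m2", "cineanthropometric", 27.4, 4.7, 0),
    list("thigh_perimeter_cm", "cineanthropometric", 47.4, 5.6, 0),
    list("calf_perimeter_cm", "cineanthropometric", 32.5, 3.5, 0),
    list("fat_mass_kg", "cineanthropometric", 24.0, 8.1, 0),
    list("fat_mass_pct", "cineanthropometric", 38.2, 7.5, 0),
    list("muscle_mass_total_kg", "cineanthropometric", 36.2, 4.4, 0),
    list("muscle_mass_appendicular_kg", "cineanthropometric", 15.4, 2.3, 0),
    list("muscle_mass_lower_limbs_kg", "cineanthropometric", 12.2, 1.3, 0),
    list("smmi_kg_m2", "cineanthropometric", 6.0, 0.8, 0),
    list("barthel_score", "functional", 95, 9, 0),
    list("sppb_score", "functional", 7.0, 2.6, 0),
    list("mna_score", "functional", 14.0, 4.5, 0),
    list("gait_speed_m_s", "functional", 0.72, 0.23, 0),
    list("handgrip_kg", "functional", 18.0, 3.9, 0),
    list("max_isotonic_knee_extension_kg", "functional", 8.37, 3.1, 0),
    list("max_isotonic_leg_press_kg", "functional", 56.7, 24.3, 0),
    list("max_isometric_knee_extension_kg", "functional", 18.7, 6.4, 0),
    list("mean_isometric_knee_extension_kg", "functional", 16.5, 6.4, 0),
    list("fvca_l_s", "respiratory", 1.86, 0.57, 0),
    list("fvcp_pct", "respiratory", 112.0, 24.5, 0),
    list("fev1a_l_s", "respiratory", 1.46, 0.42, 0),
    list("fev1p_pct", "respiratory", 116.0, 26.6, 0),
    list("fev2575a_l_s", "respiratory", 1.41, 0.69, 0),
    list("fev2575p_pct", "respiratory", 64.0, 29.5, 0),
    list("pef_l_s", "respiratory", 3.7, 1.2, 0),
    list("mip_cmh2o", "respiratory", 45.0, 20.3, 0),
    list("mep_cmh2o", "respiratory", 77.0, 28.8, 0),
    list("adc_e3mm2s", "imaging", 1.05, 0.1, 0),
    list("d_e3mm2s", "imaging", 1.01, 0.1, 0),
    list("t2star_ms", "imaging", 31.6, 4.1, 0),
    list("pdff", "imaging", 0.13, 0.03, 0),
    list("macro_infiltration", "imaging", 0.34, 0.10, 0),
    list("muscle_fat_ratio", "imaging", 0.69, 0.30, 0),
    list("muscle_bone_ratio", "imaging", 13.0, 3.2, 0),
    list("muscle_volume_l", "imaging", 1.25, 0.4, 0))
  tibble::tibble(
    variable = vapply(tribble_rows, `[[`, character(1), 1),
    block = vapply(tribble_rows, `[[`, character(1), 2),
    mean = vapply(tribble_rows, function(r) as.numeric(r[[3]]), numeric(1)),
    sd = vapply(tribble_rows, function(r) as.numeric(r[[4]]), numeric(1)),
    lower = vapply(tribble_rows, function(r) as.numeric(r[[5]]), numeric(1)))
}

#' Reference imaging-vs-clinical correlation structure
#'
#' All published pairwise correlation coefficients between the eight
#' imaging biomarkers and the cineanthropometric, functional and
#' respiratory variables (including the sub-threshold cells printed for
#' context). Pairs not listed are taken as uncorrelated before the
#' nearest positive-semi-definite repair.
#'
#' @return Tibble with columns `imaging`, `clinical`, `r`.
#' @export
ref_correlations <- function() {
  rows <- list(
    # cineanthropometric block
    c("adc_e3mm2s", "bmi_kg_m2", -0.71), c("adc_e3mm2s", "thigh_perimeter_cm", -0.32),
    c("adc_e3mm2s", "fat_mass_pct", -0.69), c("adc_e3mm2s", "muscle_mass_total_kg", -0.35),
    c("adc_e3mm2s", "smmi_kg_m2", -0.23),
    c("d_e3mm2s", "bmi_kg_m2", -0.71), c("d_e3mm2s", "thigh_perimeter_cm", -0.55),
    c("d_e3mm2s", "fat_mass_pct", -0.72), c("d_e3mm2s", "muscle_mass_total_kg", -0.62),
    c("d_e3mm2s", "smmi_kg_m2", -0.51),
    c("t2star_ms", "bmi_kg_m2", -0.62), c("t2star_ms", "thigh_perimeter_cm", -0.73),
    c("t2star_ms", "fat_mass_pct", -0.60), c("t2star_ms", "muscle_mass_total_kg", -0.25),
    c("t2star_ms", "smmi_kg_m2", -0.24),
    c("pdff", "bmi_kg_m2", 0.82), c("pdff", "thigh_perimeter_cm", 0.29),
    c("pdff", "fat_mass_pct", 0.74), c("pdff", "muscle_mass_total_kg", 0.41),
    c("pdff", "smmi_kg_m2", 0.37),
    c("macro_infiltration", "bmi_kg_m2", 0.67),
    c("macro_infiltration", "thigh_perimeter_cm", 0.46),
    c("macro_infiltration", "fat_mass_pct", 0.71),
    c("macro_infiltration", "muscle_mass_total_kg", 0.24),
    c("macro_infiltration", "smmi_kg_m2", 0.10),
    c("muscle_fat_ratio", "bmi_kg_m2", -0.61),
    c("muscle_fat_ratio", "thigh_perimeter_cm", -0.78),
    c("muscle_fat_ratio", "fat_mass_pct", -0.68),
    c("muscle_fat_ratio", "muscle_mass_total_kg", -0.35),
    c("muscle_fat_ratio", "smmi_kg_m2", -0.21),
    c("muscle_bone_ratio", "bmi_kg_m2", -0.28),
    c("muscle_bone_ratio", "thigh_perimeter_cm", -0.14),
    c("muscle_bone_ratio", "fat_mass_pct", -0.24),
    c("muscle_bone_ratio", "muscle_mass_total_kg", -0.12),
    c("muscle_bone_ratio", "smmi_kg_m2", 0.02),
    # functional block
    c("adc_e3mm2s", "handgrip_kg", -0.28),
    c("adc_e3mm2s", "mean_isometric_knee_extension_kg", -0.36),
    c("adc_e3mm2s", "max_isometric_knee_extension_kg", -0.23),
    c("adc_e3mm2s", "sppb_score", -0.28),
    c("adc_e3mm2s", "max_isotonic_leg_press_kg", -0.36),
    c("d_e3mm2s", "handgrip_kg", -0.28),
    c("d_e3mm2s", "mean_isometric_knee_extension_kg", -0.42),
    c("d_e3mm2s", "max_isometric_knee_extension_kg", -0.45),
    c("d_e3mm2s", "sppb_score", 0.02),
    c("d_e3mm2s", "max_isotonic_leg_press_kg", -0.27),
    c("t2star_ms", "handgrip_kg", -0.27),
    c("t2star_ms", "mean_isometric_knee_extension_kg", -0.02),
    c("t2star_ms", "max_isometric_knee_extension_kg", 0.03),
    c("t2star_ms", "sppb_score", -0.23),
    c("t2star_ms", "max_isotonic_leg_press_kg", -0.51),
    c("pdff", "handgrip_kg", -0.51),
    c("pdff", "mean_isometric_knee_extension_kg", -0.11),
    c("pdff", "max_isometric_knee_extension_kg", -0.21),
    c("pdff", "sppb_score", -0.27),
    c("pdff", "max_isotonic_leg_press_kg", 0.10),
    c("macro_infiltration", "handgrip_kg", -0.10),
    c("macro_infiltration", "mean_isometric_knee_extension_kg", -0.15),
    c("macro_infiltration", "max_isometric_knee_extension_kg", -0.20),
    c("macro_infiltration", "sppb_score", -0.60),
    c("macro_infiltration", "max_isotonic_leg_press_kg", 0.01),
    c("muscle_fat_ratio", "handgrip_kg", -0.18),
    c("muscle_fat_ratio", "mean_isometric_knee_extension_kg", -0.57),
    c("muscle_fat_ratio", "max_isometric_knee_extension_kg", -0.46),
    c("muscle_fat_ratio", "sppb_score", 0.11),
    c("muscle_fat_ratio", "max_isotonic_leg_press_kg", -0.18),
    c("muscle_bone_ratio", "handgrip_kg", 0.22),
    c("muscle_bone_ratio", "mean_isometric_knee_extension_kg", -0.42),
    c("muscle_bone_ratio", "max_isometric_knee_extension_kg", -0.42),
    c("muscle_bone_ratio", "sppb_score", 0.39),
    c("muscle_bone_ratio", "max_isotonic_leg_press_kg", -0.28),
    c("muscle_volume_l", "handgrip_kg", 0.50),
    c("muscle_volume_l", "mean_isometric_knee_extension_kg", 0.25),
    c("muscle_volume_l", "max_isometric_knee_extension_kg", 0.26),
    c("muscle_volume_l", "sppb_score", 0.47),
    c("muscle_volume_l", "max_isotonic_leg_press_kg", 0.10),
    # respiratory block
    c("adc_e3mm2s", "fvca_l_s", -0.44), c("adc_e3mm2s", "fev1a_l_s", -0.56),
    c("adc_e3mm2s", "fev2575a_l_s", -0.61), c("adc_e3mm2s", "pef_l_s", -0.26),
    c("adc_e3mm2s", "mip_cmh2o", -0.54), c("adc_e3mm2s", "mep_cmh2o", -0.30),
    c("d_e3mm2s", "fvca_l_s", -0.26), c("d_e3mm2s", "fev1a_l_s", -0.33),
    c("d_e3mm2s", "fev2575a_l_s", -0.55), c("d_e3mm2s", "pef_l_s", -0.18),
    c("d_e3mm2s", "mip_cmh2o", -0.10), c("d_e3mm2s", "mep_cmh2o", -0.10),
    c("t2star_ms", "fvca_l_s", -0.36), c("t2star_ms", "fev1a_l_s", -0.30),
    c("t2star_ms", "fev2575a_l_s", -0.54), c("t2star_ms", "pef_l_s", -0.10),
    c("t2star_ms", "mip_cmh2o", 0.17), c("t2star_ms", "mep_cmh2o", -0.37),
    c("pdff", "fvca_l_s", -0.21), c("pdff", "fev1a_l_s", -0.13),
    c("pdff", "fev2575a_l_s", -0.20), c("pdff", "pef_l_s", 0.03),
    c("pdff", "mip_cmh2o", 0.21), c("pdff", "mep_cmh2o", 0.08),
    c("macro_infiltration", "fvca_l_s", -0.65),
    c("macro_infiltration", "fev1a_l_s", -0.48),
    c("macro_infiltration", "fev2575a_l_s", -0.32),
    c("macro_infiltration", "pef_l_s", -0.51),
    c("macro_infiltration", "mip_cmh2o", -0.37),
    c("macro_infiltration", "mep_cmh2o", -0.25),
    c("muscle_fat_ratio", "fvca_l_s", -0.28),
    c("muscle_fat_ratio", "fev1a_l_s", -0.29),
    c("muscle_fat_ratio", "fev2575a_l_s", -0.23),
    c("muscle_fat_ratio", "pef_l_s", -0.15),
    c("muscle_fat_ratio", "mip_cmh2o", -0.35),
    c("muscle_fat_ratio", "mep_cmh2o", -0.24),
    c("muscle_bone_ratio", "fvca_l_s", 0.47),
    c("muscle_bone_ratio", "fev1a_l_s", 0.38),
    c("muscle_bone_ratio", "fev2575a_l_s", 0.29),
    c("muscle_bone_ratio", "pef_l_s", 0.18),
    c("muscle_bone_ratio", "mip_cmh2o", -0.28),
    c("muscle_bone_ratio", "mep_cmh2o", -0.01),
    c("muscle_volume_l", "fvca_l_s", 0.53),
    c("muscle_volume_l", "fev1a_l_s", 0.09),
    c("muscle_volume_l", "fev2575a_l_s", 0.18),
    c("muscle_volume_l", "pef_l_s", 0.47),
    c("muscle_volume_l", "mip_cmh2o", 0.36),
    c("muscle_volume_l", "mep_cmh2o", 0.32))
  tibble::tibble(
    imaging = vapply(rows, `[`, character(1), 1),
    clinical = vapply(rows, `[`, character(1), 2),
    r = as.numeric(vapply(rows, `[`, character(1), 3)))
}

#' The clinical variable blocks used in the correlation reports
#'
#' @return Named list of character vectors: the clinical variables of the
#'   cineanthropometric, functional and respiratory report blocks.
#' @export
report_blocks <- function() {
  list(
    cineanthropometric = c("bmi_kg_m2", "thigh_perimeter_cm", "fat_mass_pct",
                           "muscle_mass_total_kg", "smmi_kg_m2"),
    functional = c("handgrip_kg", "mean_isometric_knee_extension_kg",
                   "max_isometric_knee_extension_kg", "sppb_score",
                   "max_isotonic_leg_press_kg"),
    respiratory = c("fvca_l_s", "fev1a_l_s", "fev2575a_l_s", "pef_l_s",
                    "mip_cmh2o", "mep_cmh2o"))
}
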