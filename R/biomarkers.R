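# Reduction of label volumes and parameter maps to the eight per-subject
# imaging biomarkers: absolute muscle volume, muscle/fat and muscle/bone
# ratios, macroscopic fatty infiltration, and the voxel-mean PDFF, T2*,
# ADC and D over the muscle.

#' Tissue volumes in litres
#'
#' Voxel count times voxel volume (from the affine determinant) per
#' tissue class.
#'
#' @param labels A `label_volume` with grid metadata.
#' @return Tibble with columns `tissue` and `volume_l`, one row per class
#'   of [tissue_codes()] (absent classes have volume 0).
#' @export
tissue_volumes <- function(labels) {
  voxvol <- voxel_volume_of(labels)
  codes <- tissue_codes()
  counts <- vapply(codes, function(cd) sum(labels == cd), numeric(1))
  tibble::tibble(tissue = names(codes),
                 volume_l = unname(counts) * voxvol / 1e6)
}

#' Muscle/fat and muscle/bone volume ratios
#'
#' Fat is subcutaneous plus intramuscular fat; bone is cortical bone plus
#' marrow. A zero denominator yields `NA` (flagged), never infinity.
#'
#' @param volumes Tibble from [tissue_volumes()].
#' @return List with `muscle_fat_ratio` and `muscle_bone_ratio`.
#' @export
tissue_ratios <- function(volumes) {
  v <- setNames(volumes$volume_l, volumes$tissue)
  fat <- v[["subcutaneous_fat"]] + v[["intramuscular_fat"]]
  bone <- v[["cortical_bone"]] + v[["marrow"]]
  list(
    muscle_fat_ratio = if (fat > 0) unname(v[["muscle"]] / fat) else NA_real_,
    muscle_bone_ratio = if (bone > 0) unname(v[["muscle"]] / bone) else NA_real_)
}

#' Macroscopic fatty infiltration
#'
#' Relative volume of fat enclosed in the closed muscle envelope,
#' excluding bone: fat voxels inside the envelope divided by envelope
#' voxels minus bone voxels inside the envelope.
#'
#' @param labels A `label_volume`.
#' @param envelope Logical envelope mask from [close_muscle_mask()].
#' @return Fraction in \[0, 1\].
#' @export
macroscopic_infiltration <- function(labels, envelope) {
  if (!any(envelope)) stop("empty muscle envelope", call. = FALSE)
  codes <- tissue_codes()
  fat <- labels == codes[["subcutaneous_fat"]] |
    labels == codes[["intramuscular_fat"]]
  bone <- labels == codes[["cortical_bone"]] | labels == codes[["marrow"]]
  denom <- sum(envelope) - sum(bone & envelope)
  if (denom <= 0) stop("envelope contains no non-bone voxels", call. = FALSE)
  sum(fat & envelope) / denom
}

#' Voxel-mean of a parameter map over a tissue class
#'
#' Arithmetic mean of the unflagged map values over the class mask — the
#' per-subject summary of a voxel-wise biomarker. Flagged (non-fitted)
#' voxels are excluded, not imputed.
#'
#' @param map A `parameter_map`.
#' @param labels A `label_volume` on the map grid (resample first if
#'   needed, see [resample_mask_to_map()]).
#' @param tissue Tissue-class name, default `"muscle"`.
#' @return Scalar mean.
#' @export
summarize_map <- function(map, labels, tissue = "muscle") {
  codes <- tissue_codes()
  assert_that(tissue %in% names(codes), "unknown tissue class")
  assert_that(identical(dim(map)[1:3], dim(labels)[1:3]),
              "map and labels are on different grids")
  sel <- labels == codes[[tissue]] & !attr(map, "flagged")
  if (!any(sel)) stop("no unflagged voxels in the requested class", call. = FALSE)
  mean(map[sel])
}

#' Compute the eight imaging biomarkers for one subject
#'
#' Runs the full per-subject image analysis: segmentation of the
#' T1-weighted volume, morphological closing, PDFF/T2* and ADC/D map
#' fitting, resampling of the labels onto each map grid, and reduction to
#' the per-subject biomarker row.
#'
#' @param bundle A `series_bundle` (see [read_series()]) or a
#'   `thigh_phantom`.
#' @param closing_radius_mm Ball radius of the muscle-mask closing, mm.
#' @param min_structure_ml Small-structure exclusion threshold, ml.
#' @param k Number of intensity clusters.
#' @param b_threshold Minimum b-value of the D fit, s/mm2.
#' @param leg `"both"` (default) or `"left"`/`"right"` to restrict the
#'   analysis to one leg (split at the mid-coronal plane).
#' @param subject_id Identifier written into the output row.
#' @return One-row tibble with `subject_id` and the columns of
#'   [imaging_biomarker_names()].
#' @export
compute_imaging_biomarkers <- function(bundle, closing_radius_mm = 5,
                                       min_structure_ml = 0.5, k = 3L,
                                       b_threshold = 200, leg = "both",
                                       subject_id = "subject") {
  if (inherits(bundle, "thigh_phantom")) {
    bundle <- list(t1w = bundle$t1w, multiecho = bundle$multiecho,
                   dwi = bundle$dwi,
                   echo_times_ms = bundle$protocol$echo_times_ms,
                   b_values_s_mm2 = bundle$protocol$b_values_s_mm2,
                   subject_id = subject_id)
  }
  labels <- segment_thigh(bundle$t1w, k = k,
                          min_structure_ml = min_structure_ml)
  if (leg != "both") {
    labels <- restrict_leg(labels, leg)
  }
  envelope <- close_muscle_mask(labels, closing_radius_mm)

  vols <- tissue_volumes(labels)
  r <- tissue_ratios(vols)
  infil <- macroscopic_infiltration(labels, envelope)
  v <- setNames(vols$volume_l, vols$tissue)

  codes <- tissue_codes()
  fit_mask <- labels == codes[["muscle"]] |
    labels == codes[["intramuscular_fat"]]

  me_maps <- fit_pdff_t2star_map(bundle$multiecho, bundle$echo_times_ms,
                                 mask = fit_mask)
  dw_maps <- fit_diffusion_maps(bundle$dwi, bundle$b_values_s_mm2,
                                mask = fit_mask, b_threshold = b_threshold)

  lab_me <- resample_mask_to_map(labels, attr(bundle$multiecho, "affine") %||%
                                   attr(labels, "affine"),
                                 dim(bundle$multiecho)[1:3])
  lab_dw <- resample_mask_to_map(labels, attr(bundle$dwi, "affine") %||%
                                   attr(labels, "affine"),
                                 dim(bundle$dwi)[1:3])

  tibble::tibble(
    subject_id = bundle$subject_id %||% subject_id,
    adc_e3mm2s = summarize_map(dw_maps$adc_e3mm2s, lab_dw),
    d_e3mm2s = summarize_map(dw_maps$d_e3mm2s, lab_dw),
    t2star_ms = summarize_map(me_maps$t2star_ms, lab_me),
    pdff = summarize_map(me_maps$pdff, lab_me),
    macro_infiltration = infil,
    muscle_fat_ratio = r$muscle_fat_ratio,
    muscle_bone_ratio = r$muscle_bone_ratio,
    muscle_volume_l = unname(v[["muscle"]]))
}

# zero out the labels of the non-selected leg (legs are separated at the
# mid plane of the second axis)
restrict_leg <- function(labels, leg) {
  dm <- dim(labels)
  half <- seq_len(dm[2]) <= dm[2] / 2
  keep <- if (leg == "left") half else if (leg == "right") !half else
    stop("leg must be 'both', 'left' or 'right'", call. = FALSE)
  drop <- array(rep(!keep, each = dm[1]), dm)
  labels[drop] <- tissue_codes()[["background"]]
  labels
}
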