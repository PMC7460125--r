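# Cohort-level orchestration: sample a cohort, optionally render each
# subject as a phantom and run the imaging pipeline, then run the
# correlation reports and the IPAQ group comparison.

#' Run a synthetic cohort study
#'
#' Samples a cohort from `spec`, obtains the eight imaging biomarkers for
#' every subject — either directly from the sampler (`mode = "fast"`,
#' exercising the statistics path) or by rendering each subject as a
#' thigh phantom and running the full imaging pipeline
#' (`mode = "rendered"`, exercising the imaging path) — and then builds
#' the block-wise correlation reports and the IPAQ low/moderate group
#' comparison of the diffusion coefficient.
#'
#' @param spec A [cohort_spec()].
#' @param mode `"fast"` or `"rendered"`.
#' @param protocol Acquisition protocol used in rendered mode; a small
#'   grid keeps rendered cohorts tractable.
#' @param group_variable Variable compared between IPAQ groups.
#' @param ... Passed to [compute_imaging_biomarkers()] in rendered mode.
#' @return Object of class `cohort_study`: list with `table` (the
#'   analysis-ready results table), `reports` (a `correlation_report`),
#'   `ipaq_comparison` (a `group_comparison`) and `spec`.
#' @export
run_cohort_study <- function(spec, mode = c("fast", "rendered"),
                             protocol = acquisition_protocol(
                               grid_shape = c(96L, 192L, 8L)),
                             group_variable = "d_e3mm2s", ...) {
  mode <- match.arg(mode)
  assert_that(spec$n_subjects >= 3, "a cohort study needs n >= 3")
  table <- sample_cohort(spec)
  if (mode == "rendered") {
    table <- render_cohort(table, spec, protocol, ...)
  }
  reports <- build_correlation_report(table)
  # the group comparison needs at least two subjects per activity group
  cmp <- if (min(table(table$ipaq_category)) >= 2) {
    group_compare(table[[group_variable]], table$ipaq_category)
  } else NULL
  structure(list(table = table, reports = reports, ipaq_comparison = cmp,
                 spec = spec, mode = mode),
            class = "cohort_study")
}

# replace the sampled imaging biomarker columns with values recovered by
# rendering each subject as a phantom and running the full pipeline.
# Stacks shorter than the reference 200 mm femoral coverage render a
# proportional sub-volume; the measured muscle volume is scaled back to
# full coverage (ratios, infiltration and map means are coverage-free).
render_cohort <- function(table, spec, protocol, reference_coverage_mm = 200,
                          ...) {
  coverage <- protocol$grid_shape[3] * protocol$voxel_size_mm[3]
  scale <- coverage / reference_coverage_mm
  rows <- purrr::map_dfr(seq_len(nrow(table)), function(i) {
    subj <- table[i, ]
    params <- subject_tissue_params(subj, protocol)
    # subjects whose designed cross-section exceeds the field of view are
    # rendered at a reduced volume scale (shape-preserving) and their
    # measured volume is scaled back
    scale_i <- scale
    phantom <- NULL
    infil <- min(0.7, max(0, subj$macro_infiltration))
    # the subcutaneous ring must keep a representable thickness: cap the
    # muscle/fat ratio so that subcutaneous fat is at least a quarter of
    # the muscle volume after intramuscular fat is accounted for
    mf_max <- 1 / (infil / (1 - infil) + 0.25)
    mf <- min(mf_max, max(0.25, subj$muscle_fat_ratio))
    for (attempt in 1:5) {
      ph_spec <- phantom_spec(
        protocol = protocol, tissue_params = params,
        target_muscle_volume_l = subj$muscle_volume_l * scale_i,
        target_muscle_fat_ratio = mf,
        target_muscle_bone_ratio = min(40, max(4, subj$muscle_bone_ratio)),
        target_infiltration = infil,
        seed = spec$seed + i)
      phantom <- tryCatch(build_phantom(ph_spec), error = function(e) {
        if (grepl("infeasible", conditionMessage(e))) NULL else stop(e)
      })
      if (!is.null(phantom)) break
      scale_i <- scale_i * 0.6
    }
    if (is.null(phantom))
      stop("could not render subject ", subj$subject_id,
           " on the requested grid", call. = FALSE)
    out <- compute_imaging_biomarkers(phantom, subject_id = subj$subject_id,
                                      ...)
    out$muscle_volume_l <- out$muscle_volume_l / scale_i
    out
  })
  for (nm in imaging_biomarker_names()) table[[nm]] <- rows[[nm]]
  table
}

# muscle tissue parameters realising one subject's sampled map biomarkers
subject_tissue_params <- function(subj, protocol) {
  params <- default_tissue_params(protocol)
  pdff <- min(0.95, max(0.001, subj$pdff))
  t2s <- min(T2STAR_MAX_MS - 1, max(T2STAR_MIN_MS + 1, subj$t2star_ms))
  d <- max(0.05, subj$d_e3mm2s)
  f <- solve_perfusion_fraction(max(subj$adc_e3mm2s, d), d, 10,
                                protocol$b_values_s_mm2)
  params$muscle <- tissue_params(
    water_amplitude = 100 * (1 - pdff), fat_amplitude = 100 * pdff,
    t2star_ms = t2s, d_coeff = d, perfusion_fraction = f,
    pseudo_diffusion = 10, t1w_intensity = 500)
  params
}

#' @export
print.cohort_study <- function(x, ...) {
  cat("<cohort_study>", x$mode, "mode, n =", nrow(x$table), "\n")
  rep_cells <- sum(x$reports$reported, na.rm = TRUE)
  cat("  reported cells (|r| >", attr(x$reports, "r_threshold"), "):",
      rep_cells, "of", nrow(x$reports), "\n")
  if (!is.null(x$ipaq_comparison)) {
    cat("  IPAQ comparison (", x$ipaq_comparison$method, "): p =",
        signif(x$ipaq_comparison$p_value, 3), "\n")
  }
  invisible(x)
}
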