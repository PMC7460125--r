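# NIfTI-1 series I/O with JSON sidecars, and CSV results tables.
# Orientation convention: RAS, with the affine stored in the NIfTI qform;
# voxel volume is the absolute affine determinant. Voxel indexing is
# 0-based in world-coordinate computations; exported coordinates are mm.

write_nifti_with_grid <- function(arr, path) {
  vs <- voxel_size_of(arr)
  aff <- attr(arr, "affine") %||% default_affine(dim(arr)[1:3], vs)
  img <- RNifti::asNifti(unclass_array(arr))
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- if (nd == 4) c(vs, 1) else vs
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

unclass_array <- function(x) {
  array(as.vector(x), dim(x))
}

read_nifti_with_grid <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  arr <- array(as.vector(img), dim(img))
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  set_grid(arr, vs, matrix(aff[1:4, 1:4], 4, 4))
}

#' Write a phantom as a NIfTI series with a JSON sidecar
#'
#' Writes `t1w.nii.gz`, `multiecho.nii.gz` (4-D, echo axis 4th),
#' `dwi.nii.gz` (4-D, b axis 4th) and `truth_labels.nii.gz`, plus
#' `sidecar.json` with echo times, b-values, the label dictionary, the
#' seed and the ground-truth summary.
#'
#' @param phantom A `thigh_phantom` from [build_phantom()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_phantom_series <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(t1w = file.path(dir, "t1w.nii.gz"),
             multiecho = file.path(dir, "multiecho.nii.gz"),
             dwi = file.path(dir, "dwi.nii.gz"),
             truth_labels = file.path(dir, "truth_labels.nii.gz"),
             sidecar = file.path(dir, "sidecar.json"))
  write_nifti_with_grid(phantom$t1w, paths[["t1w"]])
  write_nifti_with_grid(phantom$multiecho, paths[["multiecho"]])
  write_nifti_with_grid(phantom$dwi, paths[["dwi"]])
  write_nifti_with_grid(phantom$truth_labels, paths[["truth_labels"]])
  sidecar <- list(
    echo_times_ms = phantom$protocol$echo_times_ms,
    b_values_s_mm2 = phantom$protocol$b_values_s_mm2,
    voxel_size_mm = phantom$protocol$voxel_size_mm,
    label_dict = as.list(tissue_codes()),
    seed = phantom$spec$seed,
    noise_sigma = phantom$spec$noise_sigma,
    truth_summary = as.list(phantom$truth_summary))
  jsonlite::write_json(sidecar, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read an MRI series bundle
#'
#' Reads the T1-weighted, multi-echo and diffusion volumes plus the JSON
#' sidecar, checks that sidecar metadata lengths match the 4th-axis
#' extents and that protocol invariants hold, and returns a bundle ready
#' for [compute_imaging_biomarkers()].
#'
#' @param dir Directory containing `t1w.nii.gz`, `multiecho.nii.gz`,
#'   `dwi.nii.gz` and `sidecar.json` (as written by
#'   [write_phantom_series()]), or a named list/vector of those paths.
#' @param subject_id Subject identifier attached to the bundle.
#' @return Object of class `series_bundle`: list with `t1w`, `multiecho`,
#'   `dwi`, `echo_times_ms`, `b_values_s_mm2`, `sidecar`, `subject_id`.
#' @export
read_series <- function(dir, subject_id = "subject") {
  if (is.character(dir) && length(dir) == 1 && dir.exists(dir)) {
    paths <- c(t1w = file.path(dir, "t1w.nii.gz"),
               multiecho = file.path(dir, "multiecho.nii.gz"),
               dwi = file.path(dir, "dwi.nii.gz"),
               sidecar = file.path(dir, "sidecar.json"))
  } else {
    paths <- unlist(dir)
  }
  for (nm in c("t1w", "multiecho", "dwi", "sidecar")) {
    assert_that(nm %in% names(paths) && file.exists(paths[[nm]]),
                paste("missing input:", nm))
  }
  sidecar <- jsonlite::read_json(paths[["sidecar"]], simplifyVector = TRUE)
  te <- as.numeric(sidecar$echo_times_ms)
  b <- as.numeric(sidecar$b_values_s_mm2)
  if (any(diff(te) <= 0) || any(te <= 0))
    stop("sidecar echo times must be positive and strictly increasing",
         call. = FALSE)
  if (b[1] != 0 || any(diff(b) <= 0))
    stop("sidecar b-values must start at 0 and increase strictly",
         call. = FALSE)
  t1w <- read_nifti_with_grid(paths[["t1w"]])
  me <- read_nifti_with_grid(paths[["multiecho"]])
  dw <- read_nifti_with_grid(paths[["dwi"]])
  if (length(dim(me)) != 4 || dim(me)[4] != length(te))
    stop("multiecho 4th axis (", paste(dim(me), collapse = "x"),
         ") does not match ", length(te), " echo times", call. = FALSE)
  if (length(dim(dw)) != 4 || dim(dw)[4] != length(b))
    stop("dwi 4th axis (", paste(dim(dw), collapse = "x"),
         ") does not match ", length(b), " b-values", call. = FALSE)
  if (!identical(dim(t1w)[1:3], dim(me)[1:3]) ||
      !identical(dim(t1w)[1:3], dim(dw)[1:3]))
    stop("spatial grids of t1w/multiecho/dwi differ on axis 1-3",
         call. = FALSE)
  structure(list(t1w = t1w, multiecho = me, dwi = dw,
                 echo_times_ms = te, b_values_s_mm2 = b,
                 sidecar = sidecar, subject_id = subject_id),
            class = "series_bundle")
}

#' Write a results table as CSV
#'
#' Stable column order, floats at 6 significant digits; re-reading gives
#' the original within print precision.
#'
#' @param table Non-empty tibble/data.frame with a `subject_id` column of
#'   unique identifiers.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_results <- function(table, path) {
  assert_that(nrow(table) >= 1, "results table is empty")
  if ("subject_id" %in% names(table) && anyDuplicated(table$subject_id))
    stop("duplicate subject_id in results table", call. = FALSE)
  out <- dplyr::mutate(as.data.frame(table),
                       dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
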