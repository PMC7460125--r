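#' Acquisition protocol for the synthetic thigh study
#'
#' Bundles the echo times of the multi-echo chemical-shift sequence, the
#' b-values of the diffusion-weighted sequence, and the reconstruction grid.
#'
#' @param echo_times_ms Numeric vector of echo times in ms, strictly
#'   increasing and positive.
#' @param b_values_s_mm2 Numeric vector of diffusion weightings in s/mm2,
#'   non-negative, strictly increasing, starting at 0.
#' @param voxel_size_mm Length-3 voxel edge lengths in mm.
#' @param grid_shape Length-3 integer voxel counts.
#' @return An object of class `acquisition_protocol`.
#' @export
#' @examples
#' p <- acquisition_protocol()
#' p$echo_times_ms
acquisition_protocol <- function(echo_times_ms = c(0.88, 1.55, 2.22, 2.89, 3.56, 4.23),
                                 b_values_s_mm2 = c(0, 50, 100, 400, 1200),
                                 voxel_size_mm = c(1.5, 1.5, 5),
                                 grid_shape = c(128L, 256L, 40L)) {
  assert_that(length(echo_times_ms) >= 1 && all(echo_times_ms > 0),
              "echo times must be positive")
  assert_that(all(diff(echo_times_ms) > 0), "echo times must be strictly increasing")
  assert_that(length(b_values_s_mm2) >= 1 && all(b_values_s_mm2 >= 0),
              "b-values must be non-negative")
  assert_that(b_values_s_mm2[1] == 0, "first b-value must be 0")
  assert_that(all(diff(b_values_s_mm2) > 0), "b-values must be strictly increasing")
  assert_that(length(voxel_size_mm) == 3 && all(voxel_size_mm > 0),
              "voxel_size_mm must be 3 positive lengths")
  assert_that(length(grid_shape) == 3 && all(grid_shape >= 1),
              "grid_shape must be 3 positive counts")
  structure(
    list(echo_times_ms = as.numeric(echo_times_ms),
         b_values_s_mm2 = as.numeric(b_values_s_mm2),
         voxel_size_mm = as.numeric(voxel_size_mm),
         grid_shape = as.integer(grid_shape)),
    class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("<acquisition_protocol>\n")
  cat("  echo times (ms):", paste(x$echo_times_ms, collapse = ", "), "\n")
  cat("  b-values (s/mm2):", paste(x$b_values_s_mm2, collapse = ", "), "\n")
  cat("  grid:", paste(x$grid_shape, collapse = " x "), "voxels at",
      paste(x$voxel_size_mm, collapse = " x "), "mm\n")
  invisible(x)
}

#' Per-tissue signal-model parameters
#'
#' Water and fat proton amplitudes (arbitrary units), effective transverse
#' relaxation time T2*, the intravoxel-incoherent-motion diffusion triplet
#' (tissue diffusion coefficient D, perfusion fraction f, pseudo-diffusion
#' D*), and a representative T1-weighted brightness.
#'
#' @param water_amplitude,fat_amplitude Non-negative signal amplitudes W, F.
#' @param t2star_ms T2* in ms, > 0.
#' @param d_coeff Tissue diffusion coefficient in 1e-3 mm2/s, >= 0.
#' @param perfusion_fraction Perfusion fraction f in \[0, 1\].
#' @param pseudo_diffusion Pseudo-diffusion D* in 1e-3 mm2/s, >= d_coeff.
#' @param t1w_intensity Representative T1-weighted brightness (a.u.).
#' @return An object of class `tissue_params`. The implied proton density
#'   fat fraction F/(W+F) is attached as `$pdff` (NA when W+F = 0).
#' @export
tissue_params <- function(water_amplitude, fat_amplitude, t2star_ms,
                          d_coeff = 0, perfusion_fraction = 0,
                          pseudo_diffusion = d_coeff, t1w_intensity = 0) {
  assert_that(water_amplitude >= 0 && fat_amplitude >= 0,
              "amplitudes must be non-negative")
  assert_that(t2star_ms > 0, "t2star_ms must be > 0")
  assert_that(d_coeff >= 0, "d_coeff must be >= 0")
  assert_that(perfusion_fraction >= 0 && perfusion_fraction <= 1,
              "perfusion_fraction must be in [0, 1]")
  assert_that(pseudo_diffusion >= d_coeff,
              "pseudo_diffusion must be >= d_coeff")
  tot <- water_amplitude + fat_amplitude
  structure(
    list(water_amplitude = water_amplitude, fat_amplitude = fat_amplitude,
         t2star_ms = t2star_ms, d_coeff = d_coeff,
         perfusion_fraction = perfusion_fraction,
         pseudo_diffusion = pseudo_diffusion,
         t1w_intensity = t1w_intensity,
         pdff = if (tot > 0) fat_amplitude / tot else NA_real_),
    class = "tissue_params")
}

#' Default tissue parameter set for the thigh phantom
#'
#' Muscle parameters reproduce the reference cohort means (PDFF 0.13,
#' T2* 31.6 ms, D 1.01e-3 mm2/s, and a perfusion fraction calibrated so
#' that the conventional all-b ADC of the noiseless signal is
#' 1.05e-3 mm2/s). Fat-like tissues are bright on T1w with high fat
#' fraction and short-range diffusion; cortical bone is dark with very
#' short T2*. Intensities follow the ordinal contrast dark bone / mid
#' muscle / bright fat and marrow.
#'
#' @param protocol An [acquisition_protocol()]; used to calibrate the
#'   muscle perfusion fraction against the protocol b-values.
#' @return Named list of [tissue_params()] keyed by tissue class.
#' @export
default_tissue_params <- function(protocol = acquisition_protocol()) {
  f_muscle <- solve_perfusion_fraction(
    adc_target = 1.05, d_coeff = 1.01, pseudo_diffusion = 10,
    b_values = protocol$b_values_s_mm2)
  list(
    background = tissue_params(0, 0, t2star_ms = 1e6, d_coeff = 0,
                               t1w_intensity = 0),
    subcutaneous_fat = tissue_params(10, 90, t2star_ms = 45, d_coeff = 0.35,
                                     t1w_intensity = 1000),
    muscle = tissue_params(87, 13, t2star_ms = 31.6, d_coeff = 1.01,
                           perfusion_fraction = f_muscle,
                           pseudo_diffusion = 10, t1w_intensity = 500),
    intramuscular_fat = tissue_params(10, 90, t2star_ms = 45, d_coeff = 0.35,
                                      t1w_intensity = 1000),
    cortical_bone = tissue_params(5, 1, t2star_ms = 2, d_coeff = 0.1,
                                  t1w_intensity = 50),
    marrow = tissue_params(8, 92, t2star_ms = 50, d_coeff = 0.3,
                           t1w_intensity = 1000)
  )
}

#' Calibrate a perfusion fraction from a target conventional ADC
#'
#' Solves for the IVIM perfusion fraction f such that the ordinary
#' least-squares log-linear slope over all protocol b-values (the
#' conventional ADC) of the noiseless bi-exponential signal equals
#' `adc_target`, given the tissue diffusion coefficient and
#' pseudo-diffusion coefficient.
#'
#' @param adc_target Target ADC in 1e-3 mm2/s.
#' @param d_coeff Tissue diffusion coefficient in 1e-3 mm2/s.
#' @param pseudo_diffusion Pseudo-diffusion D* in 1e-3 mm2/s.
#' @param b_values b-values in s/mm2 over which the ADC slope is taken.
#' @return Perfusion fraction in \[0, 1\] (0 when `adc_target <= d_coeff`).
#' @export
solve_perfusion_fraction <- function(adc_target, d_coeff, pseudo_diffusion,
                                     b_values = c(0, 50, 100, 400, 1200)) {
  if (adc_target <= d_coeff) return(0)
  adc_of <- function(f) {
    s <- f * exp(-b_values * pseudo_diffusion * 1e-3) +
      (1 - f) * exp(-b_values * d_coeff * 1e-3)
    y <- log(s)
    -1000 * coef(lm(y ~ b_values))[[2]]
  }
  stats::uniroot(function(f) adc_of(f) - adc_target,
                 lower = 0, upper = 0.5, tol = 1e-10)$root
}
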