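# Synthetic two-leg thigh phantom: designed concentric-cylinder geometry
# with known tissue ground truth, plus signal simulation for the three
# MRI series (T1-weighted, multi-echo chemical-shift, diffusion-weighted).

# Fat-water chemical-shift frequency at 3 T: single-peak fat model at
# 3.4 ppm x 127.7 MHz proton frequency, rounded to 434 Hz.
FAT_WATER_SHIFT_HZ <- 434

#' Design specification of a synthetic thigh phantom
#'
#' Holds the acquisition protocol, the per-tissue signal parameters and the
#' designed (ground-truth) values of the four volumetric biomarkers:
#' absolute muscle volume, muscle/fat ratio, muscle/bone ratio and
#' macroscopic fatty-infiltration fraction. Defaults reproduce the
#' reference cohort means (muscle 1.25 L, muscle/fat 0.69, muscle/bone
#' 13.0, infiltration 0.34).
#'
#' @param protocol An [acquisition_protocol()].
#' @param tissue_params Named list of [tissue_params()], one per tissue
#'   class of [tissue_codes()].
#' @param target_muscle_volume_l Designed muscle volume (pure muscle,
#'   excluding intramuscular fat) in litres.
#' @param target_muscle_fat_ratio Designed muscle/(subcutaneous +
#'   intramuscular fat) volume ratio.
#' @param target_muscle_bone_ratio Designed muscle/(cortical bone + marrow)
#'   volume ratio.
#' @param target_infiltration Designed intramuscular-fat fraction of the
#'   muscle compartment, in \[0, 1).
#' @param marrow_fraction Marrow share of the total bone volume.
#' @param noise_sigma Rician noise scale in signal units (0 = noiseless).
#' @param seed Integer RNG seed for speckle placement and noise.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(protocol = acquisition_protocol(grid_shape = c(96, 192, 8)),
#'                      target_muscle_volume_l = 0.25)
phantom_spec <- function(protocol = acquisition_protocol(),
                         tissue_params = default_tissue_params(protocol),
                         target_muscle_volume_l = 1.25,
                         target_muscle_fat_ratio = 0.69,
                         target_muscle_bone_ratio = 13.0,
                         target_infiltration = 0.34,
                         marrow_fraction = 0.4,
                         noise_sigma = 0,
                         seed = 20260101L) {
  assert_that(inherits(protocol, "acquisition_protocol"),
              "protocol must be an acquisition_protocol")
  assert_that(target_muscle_volume_l > 0 && target_muscle_fat_ratio > 0 &&
                target_muscle_bone_ratio > 0,
              "volume and ratio targets must be positive")
  assert_that(target_infiltration >= 0 && target_infiltration < 1,
              "target_infiltration must be in [0, 1)")
  assert_that(marrow_fraction > 0 && marrow_fraction < 1,
              "marrow_fraction must be in (0, 1)")
  assert_that(noise_sigma >= 0, "noise_sigma must be >= 0")
  need <- setdiff(names(tissue_codes()), names(tissue_params))
  assert_that(length(need) == 0,
              paste("missing tissue_params for:", paste(need, collapse = ", ")))
  structure(
    list(protocol = protocol, tissue_params = tissue_params,
         target_muscle_volume_l = target_muscle_volume_l,
         target_muscle_fat_ratio = target_muscle_fat_ratio,
         target_muscle_bone_ratio = target_muscle_bone_ratio,
         target_infiltration = target_infiltration,
         marrow_fraction = marrow_fraction,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Build the designed two-leg label geometry
#'
#' Places two concentric-cylinder legs on the protocol grid: from outside
#' in, background, subcutaneous-fat ring, muscle annulus, cortical-bone
#' shell and marrow core. Shell radii are chosen by order statistics of
#' the in-plane voxel-centre distances so that designed voxel counts are
#' met exactly up to rounding. Intramuscular fat is then placed as seeded
#' random speckle (in-plane discs of radius 1-2 voxels) inside the muscle
#' annulus until the designed infiltration fraction is reached; a
#' one-voxel guard margin keeps speckle from touching the subcutaneous
#' ring so that connectivity-based classification stays well posed.
#'
#' @param spec A [phantom_spec()].
#' @return Integer label array (a `label_volume`, see [as_label_volume()])
#'   achieving the four designed targets within voxelization error.
#' @export
make_thigh_geometry <- function(spec) {
  proto <- spec$protocol
  dm <- proto$grid_shape
  vs <- proto$voxel_size_mm
  voxvol <- prod(vs)
  nz <- dm[3]

  infil <- spec$target_infiltration
  v_mus <- spec$target_muscle_volume_l * 1e6      # mm^3 of pure muscle
  v_ann <- v_mus / (1 - infil)                    # muscle + intramuscular fat
  v_imf <- v_ann - v_mus
  v_bone <- v_mus / spec$target_muscle_bone_ratio # cortical + marrow
  v_fat <- v_mus / spec$target_muscle_fat_ratio   # subcutaneous + intramuscular
  v_sub <- v_fat - v_imf
  if (v_sub <= 0)
    stop("geometry infeasible: infiltration target exceeds the total fat budget",
         call. = FALSE)
  v_marrow <- spec$marrow_fraction * v_bone

  # cumulative per-leg per-slice voxel counts, inside out
  per_slice <- function(v) v / (2 * nz * voxvol)
  c_marrow <- round(per_slice(v_marrow))
  c_bone <- round(per_slice(v_bone))
  c_ann <- c_bone + round(per_slice(v_ann))
  c_out <- c_ann + round(per_slice(v_sub))
  if (c_marrow < 1 || c_bone - c_marrow < 1)
    stop("geometry infeasible: bone shell thinner than one voxel", call. = FALSE)

  # in-plane voxel-centre coordinates (mm) and the two leg centres
  x_mm <- (seq_len(dm[1]) - 0.5) * vs[1]
  y_mm <- (seq_len(dm[2]) - 0.5) * vs[2]
  fov <- c(dm[1] * vs[1], dm[2] * vs[2])
  centers <- list(c(fov[1] / 2, fov[2] * 0.25), c(fov[1] / 2, fov[2] * 0.75))

  r_out <- sqrt(c_out * vs[1] * vs[2] / pi)
  margin <- 2 * max(vs[1:2])
  if (r_out + margin > fov[1] / 2 || r_out + margin > fov[2] / 4)
    stop("geometry infeasible: legs do not fit on the grid", call. = FALSE)
  r_ann <- sqrt(c_ann * vs[1] * vs[2] / pi)
  if (r_out - r_ann < 2 * max(vs[1:2]))
    stop("geometry infeasible: outer fat ring thinner than two voxels",
         call. = FALSE)

  codes <- tissue_codes()
  slice <- matrix(codes[["background"]], dm[1], dm[2])
  for (ctr in centers) {
    d2 <- outer((x_mm - ctr[1])^2, (y_mm - ctr[2])^2, `+`)
    ord <- order(d2)
    slice[ord[seq_len(c_marrow)]] <- codes[["marrow"]]
    slice[ord[(c_marrow + 1):c_bone]] <- codes[["cortical_bone"]]
    slice[ord[(c_bone + 1):c_ann]] <- codes[["muscle"]]
    slice[ord[(c_ann + 1):c_out]] <- codes[["subcutaneous_fat"]]
  }
  labels <- array(rep(as.integer(slice), nz), dim = dm)

  target_imf <- round(v_imf / voxvol)
  if (target_imf > 0) {
    labels <- place_speckle(labels, target_imf, seed = spec$seed)
  }
  as_label_volume(set_grid(labels, vs))
}

# seeded random speckle of intramuscular fat inside the muscle annulus;
# a one-voxel 26-neighbourhood margin from subcutaneous fat is enforced
place_speckle <- function(labels, target_imf, seed) {
  codes <- tissue_codes()
  dm <- dim(labels)
  sub_dil <- dilate_mask(labels == codes[["subcutaneous_fat"]], unit_offsets())
  allowed <- labels == codes[["muscle"]] & !sub_dil
  if (target_imf > 0.95 * sum(allowed))
    stop("geometry infeasible: infiltration target too high for the muscle annulus",
         call. = FALSE)
  disc <- list(
    as.matrix(expand.grid(dx = -1:1, dy = -1:1))[
      rowSums(as.matrix(expand.grid(dx = -1:1, dy = -1:1))^2) <= 1, ],
    as.matrix(expand.grid(dx = -2:2, dy = -2:2))[
      rowSums(as.matrix(expand.grid(dx = -2:2, dy = -2:2))^2) <= 4, ])
  set.seed(seed)
  placed <- 0L
  while (placed < target_imf) {
    open <- which(allowed & labels == codes[["muscle"]])
    if (length(open) == 0) break
    n_batch <- max(20L, ceiling((target_imf - placed) / 9))
    ctr <- open[sample.int(length(open), min(n_batch, length(open)))]
    radii <- sample(1:2, length(ctr), replace = TRUE)
    painted <- integer(0)
    for (r in 1:2) {
      cc <- ctr[radii == r]
      if (length(cc) == 0) next
      ijk <- arrayInd(cc, dm)
      offs <- disc[[r]]
      for (o in seq_len(nrow(offs))) {
        ii <- ijk[, 1] + offs[o, 1]
        jj <- ijk[, 2] + offs[o, 2]
        ok <- ii >= 1 & ii <= dm[1] & jj >= 1 & jj <= dm[2]
        lin <- ii[ok] + dm[1] * (jj[ok] - 1) + dm[1] * dm[2] * (ijk[ok, 3] - 1)
        lin <- unique(lin[allowed[lin] & labels[lin] == codes[["muscle"]]])
        labels[lin] <- codes[["intramuscular_fat"]]
        painted <- c(painted, lin)
      }
      placed <- placed + 0L  # recounted below
    }
    placed <- sum(labels == codes[["intramuscular_fat"]])
    if (placed > target_imf) {
      # flip the most recently painted voxels back to hit the target exactly
      undo <- utils::tail(painted, placed - target_imf)
      labels[undo] <- codes[["muscle"]]
      placed <- target_imf
    }
  }
  labels
}

# magnitude of the single-peak water-fat signal at echo time te_ms
water_fat_magnitude <- function(W, F, te_ms, t2star_ms,
                                shift_hz = FAT_WATER_SHIFT_HZ) {
  theta <- 2 * pi * shift_hz * te_ms / 1000
  sqrt(W^2 + F^2 + 2 * W * F * cos(theta)) * exp(-te_ms / t2star_ms)
}

# bi-exponential intravoxel-incoherent-motion signal; d and dstar in
# 1e-3 mm2/s, b in s/mm2
ivim_signal <- function(s0, b, d, f = 0, dstar = d) {
  s0 * (f * exp(-b * dstar * 1e-3) + (1 - f) * exp(-b * d * 1e-3))
}

#' Simulate the multi-echo chemical-shift series
#'
#' Per voxel, the magnitude signal
#' `S(TE) = |W + F exp(i 2 pi df TE)| exp(-TE / T2*)` with a single-peak
#' fat resonance at `shift_hz` (434 Hz at 3 T), evaluated at the protocol
#' echo times.
#'
#' @param labels Integer label array (see [tissue_codes()]).
#' @param params Named list of [tissue_params()] for every label present.
#' @param protocol An [acquisition_protocol()].
#' @param shift_hz Fat-water chemical-shift frequency in Hz.
#' @return 4-D array, echo axis last.
#' @export
simulate_multiecho <- function(labels, params, protocol,
                               shift_hz = FAT_WATER_SHIFT_HZ) {
  check_params_cover(labels, params)
  te <- protocol$echo_times_ms
  codes <- tissue_codes()
  lut <- matrix(0, nrow = max(codes) + 1L, ncol = length(te))
  for (nm in names(params)) {
    p <- params[[nm]]
    if (!nm %in% names(codes)) next
    lut[codes[[nm]] + 1L, ] <- water_fat_magnitude(
      p$water_amplitude, p$fat_amplitude, te, p$t2star_ms, shift_hz)
  }
  out <- array(lut[as.integer(labels) + 1L, ], dim = c(dim(labels), length(te)))
  copy_grid(out, labels)
}

#' Simulate the diffusion-weighted series
#'
#' Per voxel, the bi-exponential intravoxel-incoherent-motion signal
#' `S(b) = S0 (f exp(-b D*) + (1-f) exp(-b D))`, monoexponential when
#' f = 0, evaluated at the protocol b-values. S0 is taken as W + F.
#'
#' @inheritParams simulate_multiecho
#' @return 4-D array, b-value axis last.
#' @export
simulate_dwi <- function(labels, params, protocol) {
  check_params_cover(labels, params)
  b <- protocol$b_values_s_mm2
  codes <- tissue_codes()
  lut <- matrix(0, nrow = max(codes) + 1L, ncol = length(b))
  for (nm in names(params)) {
    p <- params[[nm]]
    if (!nm %in% names(codes)) next
    s0 <- p$water_amplitude + p$fat_amplitude
    lut[codes[[nm]] + 1L, ] <- ivim_signal(s0, b, p$d_coeff,
                                           p$perfusion_fraction,
                                           p$pseudo_diffusion)
  }
  out <- array(lut[as.integer(labels) + 1L, ], dim = c(dim(labels), length(b)))
  copy_grid(out, labels)
}

check_params_cover <- function(labels, params) {
  codes <- tissue_codes()
  present <- sort(unique(as.integer(labels)))
  named <- codes[names(codes) %in% names(params)]
  miss <- setdiff(present, unname(named))
  assert_that(length(miss) == 0,
              paste("no tissue_params for label code(s):",
                    paste(miss, collapse = ", ")))
  invisible(TRUE)
}

#' Add Rician noise to a magnitude volume
#'
#' Each voxel S is replaced by `sqrt((S + g1)^2 + g2^2)` with g1, g2
#' independent zero-mean Gaussian draws of scale `sigma` — the magnitude
#' reconstruction of a complex signal with independent channel noise.
#'
#' @param volume Numeric array (any dimensionality).
#' @param sigma Noise scale in signal units, >= 0. `sigma = 0` returns the
#'   input unchanged.
#' @param seed Integer seed; a fixed seed gives reproducible output.
#' @return Array of the same shape.
#' @export
add_rician_noise <- function(volume, sigma, seed) {
  assert_that(sigma >= 0, "sigma must be >= 0")
  if (sigma == 0) return(volume)
  set.seed(as.integer(seed))
  n <- length(volume)
  out <- sqrt((volume + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  array(out, dim(volume)) |> (\(x) {attributes(x) <- attributes(volume); x})()
}

#' Render a complete synthetic thigh phantom
#'
#' Builds the designed label geometry, simulates the three image series
#' (with Rician noise at `spec$noise_sigma`), and attaches voxel-wise
#' ground-truth parameter maps plus scalar ground-truth biomarker
#' summaries recomputed from the labels with the biomarker module.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `thigh_phantom` with elements `t1w`,
#'   `multiecho`, `dwi`, `truth_labels`, `truth_maps`, `truth_summary`,
#'   `protocol` and `spec`.
#' @export
build_phantom <- function(spec) {
  proto <- spec$protocol
  labels <- make_thigh_geometry(spec)
  params <- spec$tissue_params
  codes <- tissue_codes()

  t1_lut <- numeric(max(codes) + 1L)
  for (nm in names(params)) {
    if (!nm %in% names(codes)) next
    t1_lut[codes[[nm]] + 1L] <- params[[nm]]$t1w_intensity
  }
  t1w <- array(t1_lut[as.integer(labels) + 1L], dim = dim(labels))
  t1w <- copy_grid(t1w, labels)

  me <- simulate_multiecho(labels, params, proto)
  dw <- simulate_dwi(labels, params, proto)
  if (spec$noise_sigma > 0) {
    t1w <- add_rician_noise(t1w, spec$noise_sigma, spec$seed + 1L)
    me <- add_rician_noise(me, spec$noise_sigma, spec$seed + 2L)
    dw <- add_rician_noise(dw, spec$noise_sigma, spec$seed + 3L)
  }

  truth_maps <- truth_parameter_maps(labels, params, proto)
  truth_summary <- truth_summary_from(labels, truth_maps)

  structure(
    list(t1w = t1w, multiecho = me, dwi = dw, truth_labels = labels,
         truth_maps = truth_maps, truth_summary = truth_summary,
         protocol = proto, spec = spec),
    class = "thigh_phantom")
}

# voxel-wise ground-truth maps implied by the tissue parameters; ADC and D
# are defined operationally as the log-linear slopes (all-b / high-b) of
# the clean class signal, matching the estimators of the mapping module
truth_parameter_maps <- function(labels, params, protocol,
                                 b_threshold = 200) {
  codes <- tissue_codes()
  b <- protocol$b_values_s_mm2
  hi <- b >= b_threshold
  n_code <- max(codes) + 1L
  luts <- list(pdff = rep(NA_real_, n_code), t2star_ms = rep(NA_real_, n_code),
               adc_e3mm2s = rep(NA_real_, n_code), d_e3mm2s = rep(NA_real_, n_code))
  for (nm in names(params)) {
    if (!nm %in% names(codes)) next
    p <- params[[nm]]
    i <- codes[[nm]] + 1L
    tot <- p$water_amplitude + p$fat_amplitude
    if (tot <= 0) next
    luts$pdff[i] <- p$fat_amplitude / tot
    luts$t2star_ms[i] <- p$t2star_ms
    s <- ivim_signal(1, b, p$d_coeff, p$perfusion_fraction, p$pseudo_diffusion)
    luts$adc_e3mm2s[i] <- -1000 * coef(lm(log(s) ~ b))[[2]]
    luts$d_e3mm2s[i] <- -1000 * coef(lm(log(s[hi]) ~ b[hi]))[[2]]
  }
  units <- c(pdff = "", t2star_ms = "ms", adc_e3mm2s = "1e-3 mm2/s",
             d_e3mm2s = "1e-3 mm2/s")
  maps <- lapply(names(luts), function(nm) {
    v <- array(luts[[nm]][as.integer(labels) + 1L], dim = dim(labels))
    parameter_map(copy_grid(v, labels), name = nm, units = units[[nm]],
                  flagged = is.na(v))
  })
  setNames(maps, names(luts))
}

# scalar ground truth recomputed from the labels via the biomarker module
truth_summary_from <- function(labels, truth_maps) {
  vols <- tissue_volumes(labels)
  r <- tissue_ratios(vols)
  v <- setNames(vols$volume_l, vols$tissue)
  annulus <- v[["muscle"]] + v[["intramuscular_fat"]]
  mus <- labels == tissue_codes()[["muscle"]]
  map_means <- vapply(truth_maps, function(m) mean(m[mus]), numeric(1))
  c(muscle_volume_l = unname(v[["muscle"]]),
    muscle_fat_ratio = r$muscle_fat_ratio,
    muscle_bone_ratio = r$muscle_bone_ratio,
    macro_infiltration = unname(v[["intramuscular_fat"]] / annulus),
    pdff = unname(map_means[["pdff"]]),
    t2star_ms = unname(map_means[["t2star_ms"]]),
    adc_e3mm2s = unname(map_means[["adc_e3mm2s"]]),
    d_e3mm2s = unname(map_means[["d_e3mm2s"]]))
}

#' @export
print.thigh_phantom <- function(x, ...) {
  cat("<thigh_phantom>", paste(dim(x$t1w), collapse = " x "), "voxels\n")
  cat("  noise sigma:", x$spec$noise_sigma, " seed:", x$spec$seed, "\n")
  cat("  ground truth:\n")
  print(round(x$truth_summary, 4))
  invisible(x)
}
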