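# Voxel-wise quantitative map fitting: proton density fat fraction and
# T2* from the six-echo chemical-shift series (bounded multi-start
# nonlinear least squares on the magnitude signal), ADC and D from the
# diffusion series (closed-form log-linear slopes), plus nearest-neighbour
# resampling of label masks onto a map grid.

T2STAR_MIN_MS <- 1
T2STAR_MAX_MS <- 200

#' Wrap an array as a quantitative parameter map
#'
#' @param values Numeric 3-D array with grid metadata.
#' @param name One of `"pdff"`, `"t2star_ms"`, `"adc_e3mm2s"`, `"d_e3mm2s"`.
#' @param units Unit string.
#' @param flagged Logical array marking non-fitted voxels (never
#'   zero-filled).
#' @param fit_quality Optional numeric array of per-voxel residual norms.
#' @return Object of class `parameter_map`.
#' @export
parameter_map <- function(values, name, units = "", flagged = NULL,
                          fit_quality = NULL) {
  flagged <- flagged %||% array(FALSE, dim(values))
  ok <- values[!flagged]
  if (name == "pdff")
    assert_that(all(ok >= 0 & ok <= 1), "PDFF values must lie in [0, 1]")
  if (name == "t2star_ms")
    assert_that(all(ok > 0), "T2* values must be positive")
  if (name %in% c("adc_e3mm2s", "d_e3mm2s"))
    assert_that(all(ok >= -1e-9), "diffusion coefficients must be >= 0")
  attr(values, "map_name") <- name
  attr(values, "units") <- units
  attr(values, "flagged") <- flagged
  attr(values, "fit_quality") <- fit_quality
  class(values) <- c("parameter_map", class(values))
  values
}

# unit-amplitude magnitude model shape for fat fraction p and T2* t2
# (vectorised over echoes)
wf_shape <- function(p, t2, te, theta) {
  sqrt((1 - p)^2 + p^2 + 2 * p * (1 - p) * cos(theta)) * exp(-te / t2)
}

# residual sum of squares with the overall amplitude profiled out
wf_profiled_rss <- function(p, t2, S, te, theta, ss) {
  m <- wf_shape(p, t2, te, theta)
  mm <- sum(m * m)
  a <- max(0, sum(S * m) / mm)
  ss - 2 * a * sum(S * m) + a^2 * mm
}

#' Fit PDFF and T2* from a multi-echo magnitude signal
#'
#' Bounded nonlinear least squares of the single-peak water-fat magnitude
#' model `S(TE) = |W + F exp(i 2 pi df TE)| exp(-TE/T2*)` over W >= 0,
#' F >= 0 and T2* in (1, 200] ms. The overall amplitude is profiled out
#' analytically and the optimisation runs on (PDFF, log T2*) from multiple
#' starting points on a coarse (PDFF, T2*) grid, including the fat-water
#' swapped branch; on residual ties the PDFF < 0.5 (muscle-dominant)
#' branch is preferred.
#'
#' @param signal Numeric vector of one voxel's echo magnitudes, or a
#'   matrix with one row per voxel.
#' @param echo_times_ms Echo times in ms (>= 4 echoes).
#' @param shift_hz Fat-water chemical-shift frequency in Hz.
#' @return A tibble with columns `pdff`, `t2star_ms`, `water`, `fat`,
#'   `rss`, `flagged` (no fit attempted / no convergence) and `at_bound`
#'   (solution at a box boundary).
#' @export
fit_pdff_t2star <- function(signal, echo_times_ms,
                            shift_hz = FAT_WATER_SHIFT_HZ) {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  te <- as.numeric(echo_times_ms)
  assert_that(length(te) >= 4, "at least 4 echoes are required")
  assert_that(ncol(signal) == length(te),
              "signal columns must match the number of echoes")
  assert_that(all(signal >= 0), "magnitude signal must be non-negative")
  theta <- 2 * pi * shift_hz * te / 1000

  n <- nrow(signal)
  key <- apply(signal, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  uniq <- signal[first, , drop = FALSE]
  fits <- t(apply(uniq, 1, fit_wf_voxel, te = te, theta = theta))
  res <- fits[match(key, key[first]), , drop = FALSE]
  tibble::tibble(
    pdff = res[, 1], t2star_ms = res[, 2], water = res[, 3], fat = res[, 4],
    rss = res[, 5], flagged = res[, 6] > 0, at_bound = res[, 7] > 0)
}

# single-voxel multi-start fit; returns c(pdff, t2star, W, F, rss,
# flagged, at_bound)
fit_wf_voxel <- function(S, te, theta) {
  if (all(S == 0)) return(c(NA, NA, NA, NA, Inf, 1, 0))
  ss <- sum(S * S)
  p_grid <- seq(0, 1, by = 0.1)
  t_grid <- exp(seq(log(2), log(150), length.out = 8))
  starts <- expand.grid(p = p_grid, t2 = t_grid)
  rss0 <- mapply(function(p, t2) wf_profiled_rss(p, t2, S, te, theta, ss),
                 starts$p, starts$t2)
  ord <- order(rss0)
  # greedily keep the best starts with distinct fat fractions: p = 0.5 is
  # a symmetry ridge of the magnitude model (zero gradient in p), so
  # start diversity in p is what prevents ridge-trapped solutions
  keep <- ord[!duplicated(starts$p[ord])][1:5]
  pick <- starts[keep[!is.na(keep)], ]
  pick$p[pick$p == 0.5] <- 0.48
  # always probe the fat-water swapped branch of the best start
  pick <- rbind(pick, data.frame(p = 1 - pick$p[1], t2 = pick$t2[1]))
  best <- NULL
  for (i in seq_len(nrow(pick))) {
    fit <- tryCatch(
      optim(c(pick$p[i], log(pick$t2[i])),
            function(par) wf_profiled_rss(par[1], exp(par[2]), S, te, theta, ss),
            method = "L-BFGS-B",
            lower = c(0, log(T2STAR_MIN_MS + 1e-9)),
            upper = c(1, log(T2STAR_MAX_MS)),
            control = list(factr = 10, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(c(NA, NA, NA, NA, Inf, 1, 0))
  p <- best$par[1]
  t2 <- exp(best$par[2])
  # the magnitude model is invariant under swapping W and F, so the
  # fat-dominant branch ties the water-dominant one; on (numerical) ties
  # prefer the muscle-dominant branch PDFF < 0.5
  if (p > 0.5) {
    rss_mirror <- wf_profiled_rss(1 - p, t2, S, te, theta, ss)
    if (rss_mirror <= best$value + 1e-9 * ss + 1e-12) {
      p <- 1 - p
      best$value <- rss_mirror
    }
  }
  m <- wf_shape(p, t2, te, theta)
  a <- max(0, sum(S * m) / sum(m * m))
  at_bound <- as.numeric(p < 1e-9 || p > 1 - 1e-9 ||
                           t2 <= T2STAR_MIN_MS * (1 + 1e-6) ||
                           t2 >= T2STAR_MAX_MS * (1 - 1e-9))
  # at_bound at pdff 0/1 is legitimate (pure water / pure fat); only T2*
  # bound hits are suspicious, but both are reported, never clipped
  c(p, t2, a * (1 - p), a * p, max(0, best$value), 0, at_bound)
}

#' Fit the apparent diffusion coefficient (ADC)
#'
#' Ordinary least-squares slope of `log S(b)` against b over all
#' b-values — the conventional ADC definition, perfusion-sensitive since
#' it includes b = 0.
#'
#' @param signal Numeric vector of one voxel's diffusion magnitudes, or a
#'   matrix with one row per voxel; must be strictly positive for a fit.
#' @param b_values b-values in s/mm2.
#' @return Tibble with `adc_e3mm2s` (slope in 1e-3 mm2/s), `rss` and
#'   `flagged` (non-positive signal).
#' @export
fit_adc <- function(signal, b_values) {
  fit_loglinear(signal, b_values, keep = rep(TRUE, length(b_values)),
                name = "adc_e3mm2s")
}

#' Fit the perfusion-insensitive diffusion coefficient (D)
#'
#' Ordinary least-squares log-linear fit restricted to b-values at or
#' above `b_threshold` (default 200 s/mm2), suppressing the perfusion
#' (pseudo-diffusion) contamination of the low-b signal in the
#' intravoxel-incoherent-motion framework.
#'
#' @inheritParams fit_adc
#' @param b_threshold Minimum b-value entering the fit, in s/mm2.
#' @return Tibble with `d_e3mm2s`, `rss` and `flagged`.
#' @export
fit_ivim_d <- function(signal, b_values, b_threshold = 200) {
  keep <- b_values >= b_threshold
  if (sum(keep) < 2)
    stop("fewer than 2 b-values at or above b_threshold", call. = FALSE)
  fit_loglinear(signal, b_values, keep = keep, name = "d_e3mm2s")
}

fit_loglinear <- function(signal, b_values, keep, name) {
  if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
  b <- as.numeric(b_values)
  assert_that(ncol(signal) == length(b),
              "signal columns must match the number of b-values")
  bk <- b[keep]
  x <- bk - mean(bk)
  denom <- sum(x^2)
  sk <- signal[, keep, drop = FALSE]
  flag <- apply(sk <= 0, 1, any)
  ly <- log(pmax(sk, .Machine$double.xmin))
  slope <- as.numeric(ly %*% x) / denom
  coefv <- -1000 * slope
  pred <- outer(as.numeric(rowMeans(ly)), rep(1, length(bk))) +
    outer(slope, x)
  rss <- rowSums((ly - pred)^2)
  coefv[flag] <- NA_real_
  rss[flag] <- Inf
  out <- tibble::tibble(v = coefv, rss = rss, flagged = flag)
  names(out)[1] <- name
  out
}

#' Fit PDFF and T2* maps from a 4-D multi-echo series
#'
#' Applies [fit_pdff_t2star()] to every voxel inside `mask`. Identical
#' signals (ubiquitous in noiseless phantoms) are fitted once and
#' broadcast.
#'
#' @param multiecho 4-D array, echo axis last, with grid metadata.
#' @param echo_times_ms Echo times in ms.
#' @param mask Logical array of voxels to fit (e.g. a dilated body mask);
#'   default fits voxels with any non-zero signal.
#' @return List of two `parameter_map`s: `pdff` and `t2star_ms`.
#' @export
fit_pdff_t2star_map <- function(multiecho, echo_times_ms, mask = NULL) {
  dm <- dim(multiecho)
  sig <- matrix(multiecho, ncol = dm[4])
  mask <- mask %||% array(rowSums(sig) > 0, dm[1:3])
  fits <- fit_pdff_t2star(sig[as.logical(mask), , drop = FALSE], echo_times_ms)
  build <- function(col, name, units) {
    v <- array(NA_real_, dm[1:3])
    v[as.logical(mask)] <- fits[[col]]
    fl <- array(TRUE, dm[1:3])
    fl[as.logical(mask)] <- fits$flagged
    q <- array(NA_real_, dm[1:3])
    q[as.logical(mask)] <- fits$rss
    parameter_map(copy_grid(v, multiecho), name, units, flagged = fl,
                  fit_quality = q)
  }
  list(pdff = build("pdff", "pdff", ""),
       t2star_ms = build("t2star_ms", "t2star_ms", "ms"))
}

#' Fit ADC and D maps from a 4-D diffusion series
#'
#' @param dwi 4-D array, b-value axis last, with grid metadata.
#' @param b_values b-values in s/mm2.
#' @param mask Logical array of voxels to fit; default fits voxels with a
#'   positive b = 0 signal.
#' @param b_threshold Minimum b-value of the D fit, in s/mm2.
#' @return List of two `parameter_map`s: `adc_e3mm2s` and `d_e3mm2s`.
#' @export
fit_diffusion_maps <- function(dwi, b_values, mask = NULL, b_threshold = 200) {
  dm <- dim(dwi)
  sig <- matrix(dwi, ncol = dm[4])
  mask <- mask %||% array(sig[, 1] > 0, dm[1:3])
  msk <- as.logical(mask)
  adc <- fit_adc(sig[msk, , drop = FALSE], b_values)
  dfit <- fit_ivim_d(sig[msk, , drop = FALSE], b_values, b_threshold)
  build <- function(fits, col, units) {
    v <- array(NA_real_, dm[1:3])
    v[msk] <- pmax(0, fits[[col]])
    v[msk][fits$flagged] <- NA_real_
    fl <- array(TRUE, dm[1:3])
    fl[msk] <- fits$flagged
    q <- array(NA_real_, dm[1:3])
    q[msk] <- fits$rss
    parameter_map(copy_grid(v, dwi), col, units, flagged = fl, fit_quality = q)
  }
  list(adc_e3mm2s = build(adc, "adc_e3mm2s", "1e-3 mm2/s"),
       d_e3mm2s = build(dfit, "d_e3mm2s", "1e-3 mm2/s"))
}

#' Resample a label volume onto a map grid
#'
#' Nearest-neighbour resampling of integer labels through the affine
#' mapping between the two grids (source voxel -> world mm -> target
#' voxel). For identical grids the output equals the input exactly.
#'
#' @param labels A `label_volume` with an affine.
#' @param target_affine 4x4 affine of the target grid.
#' @param target_dim Length-3 voxel counts of the target grid.
#' @return A `label_volume` on the target grid; voxels mapping outside the
#'   source become background.
#' @export
resample_mask_to_map <- function(labels, target_affine, target_dim) {
  src_aff <- attr(labels, "affine")
  assert_that(!is.null(src_aff), "source labels carry no affine")
  if (abs(det(target_affine)) < 1e-12 || abs(det(src_aff)) < 1e-12)
    stop("singular affine", call. = FALSE)
  if (identical(as.integer(target_dim), as.integer(dim(labels))) &&
      max(abs(target_affine - src_aff)) < 1e-9) {
    return(labels)
  }
  dm <- as.integer(target_dim)
  g <- expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]), k = seq_len(dm[3]))
  # voxel index (0-based) -> world; NIfTI convention
  vox <- t(cbind(g$i - 1, g$j - 1, g$k - 1, 1))
  world <- target_affine %*% vox
  src_vox <- solve(src_aff) %*% world
  idx <- round(src_vox[1:3, , drop = FALSE]) + 1
  sdm <- dim(labels)
  inside <- idx[1, ] >= 1 & idx[1, ] <= sdm[1] &
    idx[2, ] >= 1 & idx[2, ] <= sdm[2] &
    idx[3, ] >= 1 & idx[3, ] <= sdm[3]
  out <- integer(nrow(g))
  lin <- idx[1, inside] + sdm[1] * (idx[2, inside] - 1) +
    sdm[1] * sdm[2] * (idx[3, inside] - 1)
  out[inside] <- as.integer(labels)[lin]
  out <- array(out, dm)
  vsz <- sqrt(colSums(target_affine[1:3, 1:3]^2))
  out <- set_grid(out, vsz, target_affine)
  as_label_volume(out)
}
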