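test_that("PDFF/T2* fitting recovers noiseless generating parameters", {
  S <- oracle_wf_signal(87, 13, TE_REF, 31.6)
  fit <- fit_pdff_t2star(S, TE_REF)
  expect_equal(fit$pdff, 0.13, tolerance = 1e-3)
  expect_equal(fit$t2star_ms, 31.6, tolerance = 1e-3)
  expect_false(fit$flagged)

  # random noiseless voxels within the muscle-dominant branch
  set.seed(1)
  n <- 100
  p_true <- runif(n, 0.02, 0.45)
  t_true <- runif(n, 10, 80)
  a_true <- runif(n, 50, 150)
  sig <- t(sapply(seq_len(n), function(i) {
    oracle_wf_signal(a_true[i] * (1 - p_true[i]), a_true[i] * p_true[i],
                     TE_REF, t_true[i])
  }))
  fits <- fit_pdff_t2star(sig, TE_REF)
  expect_lt(max(abs(fits$pdff - p_true) / pmax(p_true, 1e-6)), 1e-3)
  expect_lt(max(abs(fits$t2star_ms - t_true) / t_true), 1e-3)
})

test_that("pure-compartment limits behave as documented", {
  # fat-free: PDFF 0 and T2* equals the monoexponential decay constant
  S <- 90 * exp(-TE_REF / 25)
  fit <- fit_pdff_t2star(S, TE_REF)
  expect_equal(fit$pdff * (1 - fit$pdff), 0, tolerance = 1e-6)
  expect_equal(fit$t2star_ms, 25, tolerance = 1e-3)
  # water-free gives the identical magnitude signal (the single-peak
  # magnitude model is W/F symmetric); the muscle-dominant tie-break
  # reports the same pure-compartment fit
  S2 <- oracle_wf_signal(0, 90, TE_REF, 25)
  fit2 <- fit_pdff_t2star(S2, TE_REF)
  expect_equal(fit2$pdff * (1 - fit2$pdff), 0, tolerance = 1e-6)
  expect_equal(fit2$t2star_ms, 25, tolerance = 1e-3)
  # all-zero voxels are flagged, not fitted
  fit3 <- fit_pdff_t2star(rep(0, 6), TE_REF)
  expect_true(fit3$flagged)
  expect_true(is.na(fit3$pdff))
})

test_that("NLS optimum agrees with exhaustive grid search", {
  set.seed(7)
  n <- 100
  for (i in seq_len(n)) {
    p <- runif(1, 0.02, 0.48)
    t2 <- runif(1, 5, 120)
    a <- runif(1, 20, 200)
    S <- oracle_wf_signal(a * (1 - p), a * p, TE_REF, t2)
    gs <- oracle_wf_gridsearch(S, TE_REF)
    fit <- fit_pdff_t2star(S, TE_REF)
    expect_true(oracle_wf_agrees(gs, fit, p, t2))
  }
})

test_that("ADC fitting matches closed-form decays", {
  s <- 100 * exp(-B_REF * 1.05e-3)
  expect_equal(fit_adc(s, B_REF)$adc_e3mm2s, 1.05, tolerance = 1e-9)
  expect_equal(fit_adc(rep(7, 5), B_REF)$adc_e3mm2s, 0, tolerance = 1e-12)
  # two-point fit is the analytic slope
  two <- fit_adc(c(100, 100 * exp(-1.2)), c(0, 1200))
  expect_equal(two$adc_e3mm2s, 1.0, tolerance = 1e-12)
  # non-positive signal is flagged
  bad <- fit_adc(c(100, 50, 10, 0, 1), B_REF)
  expect_true(bad$flagged)
  expect_true(is.na(bad$adc_e3mm2s))
})

test_that("high-b D fitting suppresses the perfusion compartment", {
  s <- 100 * exp(-B_REF * 1.01e-3)
  expect_equal(fit_ivim_d(s, B_REF)$d_e3mm2s, 1.01, tolerance = 1e-9)
  # bi-exponential with f = 0.1: two-point high-b slope computed by hand
  s2 <- 100 * (0.1 * exp(-B_REF * 10e-3) + 0.9 * exp(-B_REF * 1.01e-3))
  d_hand <- log((0.1 * exp(-4) + 0.9 * exp(-0.404)) /
                  (0.1 * exp(-12) + 0.9 * exp(-1.212))) / 800 * 1000
  fit <- fit_ivim_d(s2, B_REF)
  expect_equal(fit$d_e3mm2s, d_hand, tolerance = 1e-9)
  expect_lt(abs(fit$d_e3mm2s - 1.01) / 1.01, 0.005)  # perfusion bias < 0.5%
  expect_error(fit_ivim_d(s, B_REF, b_threshold = 1000), "fewer than 2")
})

test_that("fitters are robust at 2% Rician noise", {
  set.seed(99)
  n <- 1000
  S0 <- oracle_wf_signal(87, 13, TE_REF, 31.6)
  sig <- matrix(rep(S0, each = n), nrow = n)
  noisy <- sqrt((sig + rnorm(length(sig), 0, 2))^2 +
                  rnorm(length(sig), 0, 2)^2)
  fits <- fit_pdff_t2star(noisy, TE_REF)
  expect_lt(median(abs(fits$pdff - 0.13)), 0.02)

  d0 <- 100 * exp(-B_REF * 1.05e-3)
  sd0 <- matrix(rep(d0, each = n), nrow = n)
  noisy_d <- sqrt((sd0 + rnorm(length(sd0), 0, 2))^2 +
                    rnorm(length(sd0), 0, 2)^2)
  adc <- fit_adc(noisy_d, B_REF)
  expect_lt(median(abs(adc$adc_e3mm2s - 1.05) / 1.05), 0.05)

  # outputs always respect the physical ranges
  expect_true(all(fits$pdff >= 0 & fits$pdff <= 1))
  expect_true(all(fits$t2star_ms > 0 & fits$t2star_ms <= 200))
})

test_that("mask resampling is exact on identical grids and consistent otherwise", {
  ph <- cached_small_phantom()
  lab <- ph$truth_labels
  aff <- attr(lab, "affine")
  same <- resample_mask_to_map(lab, aff, dim(lab))
  expect_identical(as.integer(same), as.integer(lab))

  # 2x in-plane downsampling: every output label exists in the source
  aff2 <- aff
  aff2[1, 1] <- aff[1, 1] * 2
  aff2[2, 2] <- aff[2, 2] * 2
  dm2 <- c(dim(lab)[1] %/% 2, dim(lab)[2] %/% 2, dim(lab)[3])
  down <- resample_mask_to_map(lab, aff2, dm2)
  expect_true(all(as.integer(down) %in% as.integer(lab)))

  # up-then-down round trip preserves almost all labels
  affh <- aff
  affh[1, 1] <- aff[1, 1] / 2
  affh[2, 2] <- aff[2, 2] / 2
  dmh <- c(dim(lab)[1] * 2, dim(lab)[2] * 2, dim(lab)[3])
  up <- resample_mask_to_map(lab, affh, dmh)
  back <- resample_mask_to_map(up, aff, dim(lab))
  expect_gt(mean(as.integer(back) == as.integer(lab)), 0.95)

  expect_error(resample_mask_to_map(lab, matrix(0, 4, 4), dim(lab)),
               "singular")
})
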