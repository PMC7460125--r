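test_that("designed geometry achieves its volumetric targets", {
  ph <- cached_small_phantom()
  spec <- ph$spec
  truth <- ph$truth_summary
  expect_equal(truth[["muscle_volume_l"]], spec$target_muscle_volume_l,
               tolerance = 0.02)
  expect_equal(truth[["muscle_fat_ratio"]], spec$target_muscle_fat_ratio,
               tolerance = 0.02)
  expect_equal(truth[["muscle_bone_ratio"]], spec$target_muscle_bone_ratio,
               tolerance = 0.02)
  expect_equal(truth[["macro_infiltration"]], 0.34, tolerance = 0.01 / 0.34)
})

test_that("zero infiltration places no intramuscular fat", {
  lab <- make_thigh_geometry(small_phantom_spec(target_infiltration = 0))
  expect_equal(sum(lab == tissue_codes()[["intramuscular_fat"]]), 0)
})

test_that("muscle/bone ratio 1 gives equal muscle and bone volumes", {
  spec <- phantom_spec(
    protocol = acquisition_protocol(grid_shape = c(128L, 256L, 8L)),
    target_muscle_volume_l = 0.08, target_muscle_bone_ratio = 1,
    target_muscle_fat_ratio = 1, target_infiltration = 0)
  lab <- make_thigh_geometry(spec)
  codes <- tissue_codes()
  muscle <- as.numeric(sum(lab == codes[["muscle"]]))
  bone <- as.numeric(sum(lab == codes[["cortical_bone"]]) +
                       sum(lab == codes[["marrow"]]))
  expect_equal(muscle, bone, tolerance = 0.02)
})

test_that("infeasible designs raise geometry errors", {
  expect_error(make_thigh_geometry(small_phantom_spec(target_infiltration = 0.9)),
               "infeasible")
  expect_error(
    make_thigh_geometry(phantom_spec(
      protocol = acquisition_protocol(grid_shape = c(32L, 64L, 8L)))),
    "infeasible")
})

test_that("multi-echo signal matches the closed-form water-fat model", {
  proto <- acquisition_protocol(grid_shape = c(4L, 4L, 2L))
  lab <- set_grid_for_test(array(2L, c(4, 4, 2)), proto$voxel_size_mm)
  params <- default_tissue_params(proto)

  # no fat, effectively no decay: signal constant at W
  params$muscle <- tissue_params(87, 0, t2star_ms = 1e6, t1w_intensity = 500)
  me <- simulate_multiecho(lab, params, proto)
  expect_equal(as.numeric(me[1, 1, 1, ]), rep(87, 6), tolerance = 1e-4)

  # opposed phase: W = F at TE = 1/(2 * 434 Hz) gives zero before decay
  te_op <- 1000 / (2 * 434)
  proto_op <- acquisition_protocol(echo_times_ms = c(te_op, 2 * te_op),
                                   grid_shape = c(4L, 4L, 2L))
  params$muscle <- tissue_params(50, 50, t2star_ms = 31.6, t1w_intensity = 500)
  me_op <- simulate_multiecho(lab, params, proto_op)
  expect_lt(me_op[1, 1, 1, 1], 1e-8)

  # reference voxel vs independent evaluation at the protocol echoes
  params$muscle <- tissue_params(87, 13, t2star_ms = 31.6, t1w_intensity = 500)
  me_ref <- simulate_multiecho(lab, params, acquisition_protocol(
    grid_shape = c(4L, 4L, 2L)))
  expect_equal(as.numeric(me_ref[2, 3, 1, ]),
               oracle_wf_signal(87, 13, TE_REF, 31.6), tolerance = 1e-12)
})

test_that("diffusion signal follows the IVIM model", {
  proto <- acquisition_protocol(grid_shape = c(4L, 4L, 2L))
  lab <- set_grid_for_test(array(2L, c(4, 4, 2)), proto$voxel_size_mm)
  params <- default_tissue_params(proto)

  # monoexponential decay at the reference ADC when f = 0
  params$muscle <- tissue_params(100, 0, t2star_ms = 30, d_coeff = 1.05,
                                 t1w_intensity = 500)
  dw <- simulate_dwi(lab, params, proto)
  s <- as.numeric(dw[1, 1, 1, ])
  expect_equal(s / s[1], exp(-B_REF * 1.05e-3), tolerance = 1e-12)

  # b = 0 returns S0 whatever the compartments
  params$muscle <- tissue_params(60, 40, t2star_ms = 30, d_coeff = 1.01,
                                 perfusion_fraction = 0.37,
                                 pseudo_diffusion = 12, t1w_intensity = 500)
  dw2 <- simulate_dwi(lab, params, proto)
  expect_equal(dw2[1, 1, 1, 1], 100)

  # bi-exponential value at b = 400, checked against scalar evaluation
  params$muscle <- tissue_params(100, 0, t2star_ms = 30, d_coeff = 1.01,
                                 perfusion_fraction = 0.1,
                                 pseudo_diffusion = 10, t1w_intensity = 500)
  dw3 <- simulate_dwi(lab, params, proto)
  expect_equal(dw3[1, 1, 1, 4] / dw3[1, 1, 1, 1],
               0.1 * exp(-4) + 0.9 * exp(-0.404), tolerance = 1e-12)
})

test_that("noiseless signals are positive and monotone in b and TE", {
  ph <- cached_small_phantom()
  body <- ph$truth_labels != 0
  me <- matrix(ph$multiecho, ncol = dim(ph$multiecho)[4])[as.vector(body), ]
  dw <- matrix(ph$dwi, ncol = dim(ph$dwi)[4])[as.vector(body), ]
  expect_true(all(me > 0) && all(dw > 0))
  expect_true(all(apply(dw, 1, function(s) all(diff(s) <= 1e-12))))
  # fat-free tissues decay monotonically in TE
  mus <- ph$truth_labels == tissue_codes()[["cortical_bone"]]
  me_mus <- matrix(ph$multiecho, ncol = 6)[as.vector(mus), ]
  expect_true(all(diff(me_mus[1, ]) < 0))
})

test_that("Rician noise has the right null distribution and determinism", {
  x <- array(0, c(50, 50, 20))
  expect_identical(add_rician_noise(x, 0, seed = 1), x)
  noisy <- add_rician_noise(x, 1, seed = 1)
  # Rayleigh mean for S = 0, sigma = 1
  expect_equal(mean(noisy), sqrt(pi / 2), tolerance = 0.01)
  expect_identical(noisy, add_rician_noise(x, 1, seed = 1))
  expect_false(identical(noisy, add_rician_noise(x, 1, seed = 2)))
  expect_error(add_rician_noise(x, -1, seed = 1), "sigma")
})

test_that("phantom ground-truth summary is self-consistent with the labels", {
  ph <- cached_small_phantom()
  vols <- tissue_volumes(ph$truth_labels)
  r <- tissue_ratios(vols)
  v <- setNames(vols$volume_l, vols$tissue)
  expect_identical(ph$truth_summary[["muscle_volume_l"]], v[["muscle"]])
  expect_identical(ph$truth_summary[["muscle_fat_ratio"]], r$muscle_fat_ratio)
  expect_identical(ph$truth_summary[["muscle_bone_ratio"]], r$muscle_bone_ratio)
  imf <- v[["intramuscular_fat"]]
  expect_identical(ph$truth_summary[["macro_infiltration"]],
                   unname(imf / (imf + v[["muscle"]])))
})

test_that("same seed reproduces the speckle exactly", {
  a <- make_thigh_geometry(small_phantom_spec(seed = 11L))
  b <- make_thigh_geometry(small_phantom_spec(seed = 11L))
  expect_identical(as.integer(a), as.integer(b))
  c <- make_thigh_geometry(small_phantom_spec(seed = 12L))
  expect_false(identical(as.integer(a), as.integer(c)))
})
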