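test_that("intensity clustering separates well-separated populations", {
  set.seed(42)
  truth <- sample(1:3, 40 * 40 * 6, replace = TRUE)
  means <- c(50, 500, 1000)
  vol <- array(rnorm(length(truth), means[truth], 10), c(40, 40, 6))
  vol <- set_grid_for_test(vol, c(1, 1, 1))
  cl <- cluster_intensities(vol, k = 3, mask = array(TRUE, dim(vol)))
  expect_gt(mean(cl == truth), 0.999)
  expect_true(all(diff(attr(cl, "centers")) > 0))
})

test_that("clustering rejects degenerate inputs", {
  vol <- set_grid_for_test(array(7, c(10, 10, 2)), c(1, 1, 1))
  expect_error(cluster_intensities(vol, k = 3, mask = array(TRUE, dim(vol))),
               "distinct intensities")
  expect_error(cluster_intensities(vol, k = 1, mask = array(TRUE, dim(vol))),
               "k must be")
})

test_that("clustering is deterministic and ordered by intensity", {
  ph <- cached_small_phantom()
  a <- cluster_intensities(ph$t1w)
  b <- cluster_intensities(ph$t1w, seed = 999)
  expect_identical(as.integer(a), as.integer(b))
  centers <- attr(a, "centers")
  expect_true(all(diff(centers) > 0))
})

test_that("tissue assignment recovers the phantom labels", {
  for (sigma in c(0, 10)) {  # noiseless and 2% of the muscle signal
    ph <- cached_small_phantom(noise_sigma = sigma)
    seg <- assign_tissues(cluster_intensities(ph$t1w))
    codes <- tissue_codes()
    floor_dice <- if (sigma == 0) 0.95 else 0.90
    for (nm in c("subcutaneous_fat", "muscle", "intramuscular_fat",
                 "cortical_bone", "marrow")) {
      expect_gt(dice_of(seg, ph$truth_labels, codes[[nm]]), floor_dice)
    }
    # partition invariant: every voxel carries exactly one known label
    expect_true(all(as.integer(seg) %in% codes))
  }
})

test_that("zero-infiltration phantoms yield no intramuscular fat", {
  ph <- build_phantom(small_phantom_spec(target_infiltration = 0))
  seg <- assign_tissues(cluster_intensities(ph$t1w))
  expect_equal(sum(seg == tissue_codes()[["intramuscular_fat"]]), 0)
})

test_that("a bright ring touching the volume boundary is subcutaneous fat", {
  dm <- c(24, 24, 3)
  vol <- array(50, dm)
  vol[8:16, 8:16, ] <- 500          # muscle block
  vol[10:14, 10:14, ] <- 50         # dark core inside muscle
  vol[1:2, , ] <- 1000              # bright slab on the x boundary
  vol <- set_grid_for_test(vol, c(1.5, 1.5, 5))
  seg <- assign_tissues(cluster_intensities(vol))
  codes <- tissue_codes()
  expect_true(all(seg[1:2, , ] == codes[["subcutaneous_fat"]]))
  expect_equal(sum(seg == codes[["intramuscular_fat"]]), 0)
})

test_that("small-structure exclusion follows its contract", {
  ph <- cached_small_phantom()
  seg <- assign_tissues(cluster_intensities(ph$t1w))
  codes <- tissue_codes()
  expect_identical(exclude_small_structures(seg, 0), seg)
  imf_before <- sum(seg == codes[["intramuscular_fat"]])
  seg2 <- exclude_small_structures(seg, 0.5)
  expect_lte(sum(seg2 == codes[["intramuscular_fat"]]), imf_before)
  # a 2-voxel speck is far below a 1 ml threshold
  lab <- array(codes[["muscle"]], c(12, 12, 3))
  lab[6, 6, 2] <- lab[6, 7, 2] <- codes[["intramuscular_fat"]]
  lab <- as_label_volume(set_grid_for_test(lab, c(1.5, 1.5, 5)))
  out <- exclude_small_structures(lab, 1)
  expect_equal(sum(out == codes[["intramuscular_fat"]]), 0)
})

test_that("muscle-mask closing is idempotent and covers enclosed fat", {
  ph <- cached_small_phantom()
  seg <- assign_tissues(cluster_intensities(ph$t1w))
  env <- close_muscle_mask(seg, 5)
  codes <- tissue_codes()
  mask <- seg == codes[["muscle"]] | seg == codes[["intramuscular_fat"]]
  expect_true(all(env[mask]))  # superset of the input mask
  env2 <- close_muscle_mask(set_grid_for_test(env, c(1.5, 1.5, 5)), 5)
  expect_identical(as.logical(env2), as.logical(env))  # idempotence
  # envelope covers essentially all designed speckle voxels
  speckle <- ph$truth_labels == codes[["intramuscular_fat"]]
  expect_gt(sum(env & speckle) / sum(speckle), 0.99)
})

test_that("closing a solid box leaves it unchanged", {
  m <- array(FALSE, c(30, 30, 8))
  m[8:22, 8:22, 3:6] <- TRUE
  m <- set_grid_for_test(m, c(1.5, 1.5, 5))
  out <- close_muscle_mask(m, 5)
  expect_identical(as.logical(out), as.logical(m))
})
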