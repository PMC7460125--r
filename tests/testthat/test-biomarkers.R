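test_that("tissue volumes convert voxel counts to litres", {
  codes <- tissue_codes()
  lab <- array(codes[["muscle"]], c(10, 10, 10))
  lab <- as_label_volume(set_grid_for_test(lab, c(1, 1, 1)))
  v <- tissue_volumes(lab)
  expect_equal(v$volume_l[v$tissue == "muscle"], 0.001)
  expect_equal(v$volume_l[v$tissue == "marrow"], 0)     # absent class
  expect_equal(sum(v$volume_l), 0.001)
})

test_that("volume ratios handle zero denominators with flags", {
  v <- tibble::tibble(
    tissue = names(tissue_codes()),
    volume_l = c(0, 0.5, 1, 0.5, 0.05, 0.05))
  r <- tissue_ratios(v)
  expect_equal(r$muscle_fat_ratio, 1)
  expect_equal(r$muscle_bone_ratio, 10)
  v0 <- v
  v0$volume_l[v0$tissue %in% c("cortical_bone", "marrow")] <- 0
  expect_true(is.na(tissue_ratios(v0)$muscle_bone_ratio))
})

test_that("macroscopic infiltration obeys its limiting cases", {
  codes <- tissue_codes()
  lab <- array(codes[["muscle"]], c(8, 8, 4))
  lab <- as_label_volume(set_grid_for_test(lab, c(1, 1, 1)))
  env <- array(TRUE, dim(lab))
  expect_equal(macroscopic_infiltration(lab, env), 0)
  lab_fat <- array(codes[["intramuscular_fat"]], dim(lab))
  lab_fat <- as_label_volume(set_grid_for_test(lab_fat, c(1, 1, 1)))
  expect_equal(macroscopic_infiltration(lab_fat, env), 1)
  expect_error(macroscopic_infiltration(lab, array(FALSE, dim(lab))), "empty")
})

test_that("map summaries average unflagged voxels within a class", {
  codes <- tissue_codes()
  lab <- array(codes[["muscle"]], c(6, 6, 2))
  lab[1:3, , ] <- codes[["subcutaneous_fat"]]
  lab <- as_label_volume(set_grid_for_test(lab, c(1, 1, 1)))
  vals <- array(0.5, dim(lab))
  vals[1, 1, 1] <- 0.9
  flag <- array(FALSE, dim(lab))
  m <- parameter_map(set_grid_for_test(vals, c(1, 1, 1)), "pdff", "",
                     flagged = flag)
  expect_equal(summarize_map(m, lab, "muscle"), 0.5)
  # flagged voxels are excluded, not imputed
  vals2 <- array(0.5, dim(lab))
  vals2[4, 1, 1] <- 0.9
  flag2 <- array(FALSE, dim(lab))
  flag2[4, 1, 1] <- TRUE
  m2 <- parameter_map(set_grid_for_test(vals2, c(1, 1, 1)), "pdff", "",
                      flagged = flag2)
  expect_equal(summarize_map(m2, lab, "muscle"), 0.5)
  expect_error(summarize_map(m, lab, "marrow"), "no unflagged voxels")
  # boundedness of the mean
  mus <- lab == codes[["muscle"]]
  expect_true(summarize_map(m, lab, "muscle") >= min(vals[mus]) &&
                summarize_map(m, lab, "muscle") <= max(vals[mus]))
})

test_that("the full pipeline recovers the designed biomarkers", {
  ph <- cached_small_phantom()
  row <- compute_imaging_biomarkers(ph, subject_id = "phantom01")
  truth <- ph$truth_summary
  rel <- function(est, tr) abs(est - tr) / abs(tr)
  expect_lt(rel(row$muscle_volume_l, truth[["muscle_volume_l"]]), 0.05)
  expect_lt(rel(row$muscle_fat_ratio, truth[["muscle_fat_ratio"]]), 0.05)
  expect_lt(rel(row$muscle_bone_ratio, truth[["muscle_bone_ratio"]]), 0.05)
  expect_lt(rel(row$macro_infiltration, truth[["macro_infiltration"]]), 0.05)
  expect_lt(rel(row$pdff, truth[["pdff"]]), 0.02)
  expect_lt(rel(row$t2star_ms, truth[["t2star_ms"]]), 0.02)
  expect_lt(rel(row$adc_e3mm2s, truth[["adc_e3mm2s"]]), 0.02)
  expect_lt(rel(row$d_e3mm2s, truth[["d_e3mm2s"]]), 0.02)
})

test_that("recovered infiltration is monotone in the designed fraction", {
  levels <- c(0.05, 0.15, 0.25, 0.34, 0.45)
  got <- vapply(levels, function(tf) {
    lab <- make_thigh_geometry(small_phantom_spec(target_infiltration = tf))
    env <- close_muscle_mask(lab, 5)
    macroscopic_infiltration(lab, env)
  }, numeric(1))
  expect_true(all(diff(got) > 0))
  expect_equal(got, levels, tolerance = 0.05)
})

test_that("single-leg analysis halves the muscle volume", {
  ph <- cached_small_phantom()
  both <- compute_imaging_biomarkers(ph)
  left <- compute_imaging_biomarkers(ph, leg = "left")
  expect_equal(left$muscle_volume_l, both$muscle_volume_l / 2,
               tolerance = 0.05)
  expect_equal(left$macro_infiltration, both$macro_infiltration,
               tolerance = 0.05)
})
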