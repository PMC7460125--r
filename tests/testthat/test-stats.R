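test_that("the normality gate separates Gaussian from skewed samples", {
  set.seed(1)
  expect_equal(normality_gate(rnorm(200)), "normal")
  # Monte-Carlo rejection rate of a log-normal sample
  rej <- mean(vapply(1:100, function(i) {
    normality_gate(exp(rnorm(100))) == "non_normal"
  }, logical(1)))
  expect_gt(rej, 0.95)
  expect_equal(normality_gate(rep(3, 10)), "non_normal")
  expect_error(normality_gate(c(1, 2)), "n >= 3")
})

test_that("correlation cells follow the gate, stars and reporting filter", {
  set.seed(2)
  x <- rnorm(30)
  cell <- correlate(x, 2 * x + 1)
  expect_equal(cell$r, 1, tolerance = 1e-12)
  expect_equal(cell$method, "pearson")
  expect_equal(cell$stars, "***")
  expect_true(cell$reported)

  xs <- exp(rnorm(30, sd = 2))
  cell2 <- correlate(xs, exp(-xs))
  expect_equal(cell2$method, "spearman")
  expect_equal(cell2$r, -1)

  expect_true(correlate(rep(1, 10), rnorm(10))$flagged)
})

test_that("Spearman matches the rank-difference formula on 6-point samples", {
  set.seed(3)
  for (i in 1:25) {
    x <- sample(100, 6)  # distinct values, no ties
    y <- sample(100, 6)
    got <- correlate(x, y, method = "spearman")$r
    expect_equal(got, oracle_spearman(x, y), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  x <- rnorm(20)
  y <- rnorm(20)
  r0 <- correlate(x, y, method = "spearman")$r
  expect_equal(correlate(exp(x), y^3 + 5 * y, method = "spearman")$r, r0)
})

test_that("group comparison selects tests and matches exact enumeration", {
  set.seed(4)
  # identical groups: U at its null mean, p near 1
  v <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("a", "b"), each = 4)
  cmp <- group_compare(v, g)
  expect_gt(cmp$p_value, 0.85)

  # fully separated tiny groups: U = 0, exact two-sided p = 0.1
  cmp2 <- group_compare(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3),
                        method = "mann_whitney_u")
  expect_equal(cmp2$method, "mann_whitney_u")
  expect_equal(cmp2$p_value, 0.1, tolerance = 1e-12)

  # agreement with exhaustive rank-permutation enumeration for all
  # group sizes up to 6 (tie-free samples)
  for (n1 in 2:6) for (n2 in n1:6) {
    x <- sample(1000, n1)
    y <- sample(1000, n2)
    cmp3 <- group_compare(c(x, y), rep(c("a", "b"), c(n1, n2)),
                          method = "mann_whitney_u")
    expect_equal(cmp3$p_value, oracle_mw_exact(x, y), tolerance = 1e-12)
    expect_equal(cmp3$statistic, oracle_mw_u(x, y))
  }

  expect_error(group_compare(1:5, c("a", "a", "a", "a", "b")), "size >= 2")
})

test_that("the IPAQ-style group difference is detectable with fair power", {
  set.seed(5)
  hits <- vapply(1:400, function(i) {
    low <- rnorm(8, 0.81, 0.08)
    mod <- rnorm(18, 0.90, 0.15)
    cmp <- group_compare(c(low, mod), rep(c("low", "moderate"), c(8, 18)))
    cmp$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.2)   # clearly above the 5% type-I rate
  expect_lt(mean(hits), 0.95)  # a modest effect at this sample size
})

test_that("correlation reports gate per variable and filter on |r|", {
  spec <- cohort_spec(n_subjects = 26, seed = 20)
  coh <- sample_cohort(spec)
  rep <- build_correlation_report(coh)
  expect_s3_class(rep, "correlation_report")
  expect_setequal(unique(rep$block),
                  c("cineanthropometric", "functional", "respiratory"))
  expect_true(all(rep$reported == (abs(rep$r) > 0.4), na.rm = TRUE))
  expect_true(all(rep$stars[!is.na(rep$p_value) & rep$p_value < 0.001] == "***"))
  expect_true(all(abs(rep$r) <= 1, na.rm = TRUE))
  # coefficient symmetric under swapping the variable roles
  cell_xy <- correlate(coh$bmi_kg_m2, coh$adc_e3mm2s)
  cell_yx <- correlate(coh$adc_e3mm2s, coh$bmi_kg_m2)
  expect_equal(cell_xy$r, cell_yx$r)
  expect_error(build_correlation_report(coh, blocks = list(x = "nope")),
               "unknown column")
  # matrix layout carries one row per imaging biomarker
  wide <- report_matrix(rep, "cineanthropometric")
  expect_equal(nrow(wide), length(imaging_biomarker_names()))
})

test_that("tidy, glance and autoplot methods work on the result objects", {
  spec <- cohort_spec(n_subjects = 26, seed = 21)
  coh <- sample_cohort(spec)
  rep <- build_correlation_report(coh)
  td <- tidy(rep)
  expect_false(inherits(td, "correlation_report"))
  gl <- glance(rep)
  expect_equal(gl$n_cells, nrow(rep))
  cmp <- group_compare(coh$d_e3mm2s, coh$ipaq_category)
  expect_equal(nrow(tidy(cmp)), 2)
  expect_equal(glance(cmp)$p_value, cmp$p_value)
  p1 <- ggplot2::autoplot(rep)
  expect_s3_class(p1, "ggplot")
  ph <- cached_small_phantom()
  p2 <- ggplot2::autoplot(ph$truth_maps$pdff)
  expect_s3_class(p2, "ggplot")
})
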