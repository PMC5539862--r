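test_that("projection directions are unit vectors with the sphere marginal", {
  mat <- matrix(rnorm(60), nrow = 20, ncol = 3)
  rp <- random_projections(mat, k = 10000, seed = 1)
  expect_equal(sqrt(colSums(rp$directions^2)), rep(1, 10000),
               tolerance = 1e-12)
  # first coordinate of a uniform direction on the 2-sphere is U(-1, 1)
  ks <- stats::ks.test(rp$directions[1, ], "punif", -1, 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("identical curves give constant projections and the rp test degenerates", {
  mat <- matrix(rep(sin(1:25), each = 9), nrow = 9, byrow = FALSE)
  rp <- random_projections(mat, k = 5, seed = 2)
  expect_equal(apply(rp$projections, 2, function(v) diff(range(v))),
               rep(0, 5))
  w <- make_windows(mat, rep(stage_levels(), each = 3))
  expect_error(anova_rp(w, k = 3, seed = 2), "zero within-group variance")
})

test_that("FDR-combined p never exceeds the Bonferroni-combined p", {
  withr::local_seed(3)
  for (i in 1:10) {
    mat <- null_curve_matrix(18, 15)
    mat[13:18, ] <- mat[13:18, ] + runif(1, 0, 2)
    w <- make_windows(mat, rep(stage_levels(), each = 6))
    pb <- anova_rp(w, k = 12, combine = "bonferroni", seed = i)$p_value
    pf <- anova_rp(w, k = 12, combine = "fdr", seed = i)$p_value
    expect_lte(pf, pb)
  }
})

test_that("projection ANOVA is level-controlled under the null", {
  withr::local_seed(4)
  n_sets <- 200
  rej <- vapply(seq_len(n_sets), function(i) {
    w <- make_windows(null_curve_matrix(24, 15), rep(stage_levels(), each = 8))
    anova_rp(w, k = 10, combine = "bonferroni", seed = 1000 + i)$p_value <= 0.05
  }, logical(1))
  # Bonferroni is conservative: at most nominal level plus 2 binomial SEs
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / n_sets))
})

test_that("projection ANOVA rejects strongly separated groups", {
  withr::local_seed(5)
  for (i in 1:50) {
    mat <- null_curve_matrix(18, 15)
    mat[7:12, ] <- mat[7:12, ] + 25
    mat[13:18, ] <- mat[13:18, ] + 50
    w <- make_windows(mat, rep(stage_levels(), each = 6))
    expect_lt(anova_rp(w, k = 30, seed = i)$p_value, 0.001)
  }
})

test_that("max-F statistic equals a brute-force per-point computation", {
  withr::local_seed(6)
  groups <- list(matrix(rnorm(15), 3, 5), matrix(rnorm(15), 3, 5),
                 matrix(rnorm(15) + 1, 3, 5))
  w <- make_windows(do.call(rbind, groups), rep(stage_levels(), each = 3))
  res <- anova_maxf(w, B = 9, seed = 1)
  expect_equal(res$statistic, max(bf_pointwise_F(groups)), tolerance = 1e-10)
})

test_that("pointwise F is invariant to adding a common curve everywhere", {
  withr::local_seed(7)
  mat <- null_curve_matrix(12, 10)
  common <- cos(1:10)
  w1 <- make_windows(mat, rep(stage_levels(), each = 4))
  w2 <- make_windows(sweep(mat, 2, common, "+"),
                     rep(stage_levels(), each = 4))
  expect_equal(anova_maxf(w1, B = 1, seed = 1)$statistic,
               anova_maxf(w2, B = 1, seed = 1)$statistic, tolerance = 1e-10)
})

test_that("max-F test is calibrated under the null", {
  # group sizes comparable to the study's 41/100/46 curves per stage; the
  # bootstrap null approximation needs moderate groups
  withr::local_seed(8)
  n_sets <- 200
  rej <- vapply(seq_len(n_sets), function(i) {
    w <- make_windows(null_curve_matrix(75, 12), rep(stage_levels(), each = 25))
    anova_maxf(w, B = 199, seed = 2000 + i)$p_value <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 2 * sqrt(0.05 * 0.95 / n_sets))
})

test_that("bootstrap p-value hits its floor when the statistic dominates", {
  withr::local_seed(9)
  mat <- rbind(matrix(rnorm(60, 0, 0.05), 6, 10),
               matrix(rnorm(60, 50, 0.05), 6, 10),
               matrix(rnorm(60, 100, 0.05), 6, 10))
  w <- make_windows(mat, rep(stage_levels(), each = 6))
  expect_equal(anova_maxf(w, B = 999, seed = 1)$p_value, 0.001)
  expect_equal(l2_mean_test(w, c("early", "late"), B = 999,
                            seed = 1)$p_value, 0.001)
})

test_that("L2 statistic: identity case and constant-curve closed form", {
  mat <- rbind(matrix(rep(sin(1:20), 3), 3, byrow = TRUE),
               matrix(rep(sin(1:20), 3), 3, byrow = TRUE))
  w <- make_windows(mat, rep(c("early", "middle"), each = 3))
  res <- l2_mean_test(w, c("early", "middle"), B = 99, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  l <- 13
  mat2 <- rbind(matrix(2.5, 4, l), matrix(-1, 4, l))
  w2 <- make_windows(mat2, rep(c("middle", "late"), each = 4))
  res2 <- l2_mean_test(w2, c("middle", "late"), B = 9, seed = 1)
  expect_equal(res2$statistic, (2.5 - (-1))^2 * (l - 1), tolerance = 1e-12)
})

test_that("L2 test is calibrated under the null with uniform p-values", {
  withr::local_seed(10)
  n_sets <- 200
  p <- vapply(seq_len(n_sets), function(i) {
    w <- make_windows(null_curve_matrix(50, 12), rep(c("early", "middle"),
                                                     each = 25))
    l2_mean_test(w, c("early", "middle"), B = 199, seed = 3000 + i)$p_value
  }, numeric(1))
  expect_true(all(p >= 1 / 200 & p <= 1))
  expect_lt(abs(mean(p <= 0.05) - 0.05), 2 * sqrt(0.05 * 0.95 / n_sets))
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("repeated_test with a single repetition is the single p-value", {
  curves <- interpolate_to_seconds(
    generate_cohort(test_config("none", n_per_stage = 2L, recs = 2L,
                                duration_range = c(20, 30)), seed = 11))
  s <- repeated_test(curves, "x", "l2", n_reps = 1, seed = 12,
                     stages = c("early", "middle"), B = 99)
  expect_equal(s$mean, s$p_values[1])
  expect_equal(s$sd, 0)
  expect_equal(s$prop_le_05, as.numeric(s$p_values[1] <= 0.05))
})

test_that("rejection rate increases with the stage effect size", {
  props <- vapply(c("none", "moderate", "large"), function(eff) {
    curves <- interpolate_to_seconds(
      generate_cohort(test_config(eff, n_per_stage = 3L, recs = 3L,
                                  duration_range = c(30, 60)), seed = 13))
    repeated_test(curves, "x", "l2", n_reps = 100, seed = 14,
                  stages = c("early", "late"), B = 49)$prop_le_05
  }, numeric(1))
  expect_true(all(diff(props) >= 0))
  expect_lt(props[["none"]], 0.3)
  expect_equal(props[["large"]], 1)
})

test_that("window extraction stays inside each curve's grid", {
  curves <- interpolate_to_seconds(
    generate_cohort(test_config("none", n_per_stage = 2L, recs = 2L,
                                duration_range = c(20, 60)), seed = 15))
  w <- random_windows(curves, "z", n_reps = 20, seed = 16)
  l <- attr(w, "window_length")
  ti <- curves$t_end[match(w$recording_id, curves$recording_id)]
  expect_true(all(w$offset + l <= ti))
  expect_true(all(w$offset >= 0))
})
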