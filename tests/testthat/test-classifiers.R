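# separable two-feature toy with patient structure: 40 patients x 5
# recordings, cluster centres far apart relative to the noise
toy_features <- function(seed = 1, n_pat = 40L, sep = 6) {
  withr::with_seed(seed, {
    stage <- sample(rep(stage_levels(), length.out = n_pat))
    centre <- cbind(c(0, sep, 2 * sep)[match(stage, stage_levels())],
                    c(0, -sep, sep)[match(stage, stage_levels())])
    rows <- purrr::map(seq_len(n_pat), function(i) {
      tibble::tibble(
        recording_id = sprintf("p%02d_r%d", i, 1:5),
        patient_id = sprintf("p%02d", i),
        stage = stage[i],
        f1 = centre[i, 1] + rnorm(5),
        f2 = centre[i, 2] + rnorm(5))
    })
    dplyr::bind_rows(rows)
  })
}

test_that("splits never separate a patient's recordings", {
  cohort <- generate_cohort(cohort_config(), seed = 1)
  for (s in c(3, 17)) {
    sp <- split_cohort(cohort, 0.2, seed = s)
    expect_length(intersect(sp$train_patients, sp$test_patients), 0)
    sides <- ifelse(cohort$patient_id %in% sp$test_patients, "test", "train")
    expect_true(all(tapply(sides, cohort$patient_id,
                           function(v) length(unique(v)) == 1)))
    train_stages <- unique(as.character(
      cohort$stage[cohort$patient_id %in% sp$train_patients]))
    expect_setequal(train_stages, stage_levels())
  }
})

test_that("a 29/6-patient split of the default cohort is attainable", {
  cohort <- generate_cohort(cohort_config(), seed = 1)
  shapes <- vapply(1:30, function(s) {
    length(split_cohort(cohort, 0.2, seed = s)$test_patients)
  }, numeric(1))
  expect_true(6 %in% shapes)
})

test_that("zero test fraction puts every patient in training", {
  cohort <- generate_cohort(test_config("none", n_per_stage = 2L, recs = 2L,
                                        duration_range = c(20, 30)), seed = 2)
  sp <- split_cohort(cohort, 0, seed = 3)
  expect_length(sp$test_patients, 0)
  expect_setequal(sp$train_patients, unique(cohort$patient_id))
})

test_that("the network learns a separable toy and is seed-deterministic", {
  feats <- toy_features(seed = 4)
  m <- train_nn(feats, hidden = 8, seed = 5, max_iter = 500)
  acc <- mean(predict(m, feats) == as_stage_helper(feats$stage))
  expect_gte(acc, 0.95)
  m2 <- train_nn(feats, hidden = 8, seed = 5, max_iter = 500)
  expect_identical(m$weights, m2$weights)
  m3 <- train_nn(feats, hidden = 8, seed = 6, max_iter = 500)
  expect_false(identical(m$weights, m3$weights))
})

test_that("the softmax encoding also learns the separable toy", {
  feats <- toy_features(seed = 4)
  m <- train_nn(feats, hidden = 8, seed = 5, max_iter = 500,
                encoding = "softmax")
  acc <- mean(predict(m, feats) == as_stage_helper(feats$stage))
  expect_gte(acc, 0.95)
})

test_that("constant features give constant majority predictions", {
  # study-like unbalanced stages (7/18/10 patients, middle the majority)
  feats <- tibble::tibble(
    recording_id = sprintf("r%d", 1:70),
    patient_id = sprintf("p%02d", rep(1:35, each = 2)),
    stage = rep(rep(stage_levels(), c(7, 18, 10)), each = 2),
    f1 = 1, f2 = -2)
  m <- train_nn(feats, hidden = 4, seed = 8, max_iter = 200)
  preds <- predict(m, feats)
  expect_length(unique(preds), 1)
  base <- max(table(feats$stage)) / nrow(feats)
  expect_equal(mean(preds == as_stage_helper(feats$stage)), base)
})

test_that("non-finite features are rejected", {
  feats <- toy_features(seed = 9)
  feats$f1[3] <- NA
  expect_error(train_nn(feats, hidden = 4, seed = 1), "non-finite")
})

test_that("patient majority vote and tie-breaks", {
  feats <- toy_features(seed = 10)
  m <- train_nn(feats, hidden = 8, seed = 11, max_iter = 500)
  rep_ <- classify_patients(m, feats, method = "nn")
  expect_equal(sum(rep_$by_stage$n[rep_$by_stage$stage != "total"]),
               dplyr::n_distinct(feats$patient_id))
  # majority rule on synthetic vote patterns
  expect_equal(as.character(
    stagewalk:::majority_vote(c("middle", "middle", "late"))), "middle")
  prev <- c(early = 0.2, middle = 0.5, late = 0.3)
  expect_equal(as.character(
    stagewalk:::majority_vote(c("early", "late"), prev)), "late")
  expect_equal(as.character(
    stagewalk:::majority_vote(c("early", "late"))), "early")
})

test_that("report success rates recompute from the confusion counts", {
  feats <- toy_features(seed = 12)
  sp <- split_cohort(feats, 0.2, seed = 13)
  m <- train_nn(split_side(feats, sp, "train"), hidden = 8, seed = 14,
                max_iter = 500)
  rep_ <- classify_patients(m, split_side(feats, sp, "test"))
  bs <- rep_$by_stage[rep_$by_stage$stage != "total", ]
  nonzero <- bs$n > 0
  expect_equal(bs$success_rate[nonzero],
               (bs$n[nonzero] - bs$misclassified[nonzero]) / bs$n[nonzero])
})

test_that("standardisation statistics come from the training side only", {
  feats <- toy_features(seed = 15)
  sp <- split_cohort(feats, 0.2, seed = 16)
  tr <- split_side(feats, sp, "train")
  m <- train_nn(tr, hidden = 4, seed = 17, max_iter = 50)
  expect_equal(unname(m$center), unname(colMeans(as.matrix(tr[, c("f1", "f2")]))))
  expect_equal(unname(m$scale), unname(apply(as.matrix(tr[, c("f1", "f2")]), 2, sd)))
})

test_that("baselines recover a separable fixture and report all methods", {
  feats <- toy_features(seed = 18)
  sp <- split_cohort(feats, 0.2, seed = 19)
  reports <- stage_baselines(feats, sp, seed = 20)
  expect_setequal(names(reports), c("tree", "forest", "svm"))
  for (r in reports) expect_gte(glance(r)$success_rate, 0.8)
})

test_that("degenerate constant features send baselines to the base rate", {
  feats <- toy_features(seed = 21)
  feats$f1 <- 0
  feats$f2 <- 0
  sp <- split_cohort(feats, 0.25, seed = 22)
  reports <- stage_baselines(feats, sp, seed = 23)
  test_pat <- dplyr::distinct(split_side(feats, sp, "test"), patient_id,
                              stage)
  base <- mean(test_pat$stage ==
                 names(which.max(table(split_side(feats, sp, "train")$stage))))
  for (r in reports) expect_equal(glance(r)$success_rate, base)
})

test_that("layer sweep has the right shape and nails a separable fixture", {
  feats <- toy_features(seed = 24, n_pat = 18L)
  sp <- split_cohort(feats, 0.25, seed = 25)
  sw <- layer_sweep(feats, sp, layers = 1:2, n_networks = 3,
                    hidden_total = 8, seed = 26, max_iter = 300)
  expect_equal(nrow(sw), 2 * 3)
  expect_true(all(sw$misclassification >= 0 & sw$misclassification <= 1))
  expect_equal(min(sw$misclassification), 0)
  smry <- tidy(sw)
  expect_equal(smry$n_networks, c(3L, 3L))
})

test_that("the network outperforms the baselines at the full study scale", {
  # full study composition (35 patients / 187 recordings), stage effects in
  # the xy-plane; average patient-level accuracy over repeated splits
  cfg <- cohort_config(
    stage_shift = rbind(early = c(0, 0, 0), middle = c(10, 9, 0.1),
                        late = c(20, 18, 0.2)),
    gait_amplitude = rbind(early = c(1, 1, 0.3), middle = c(2, 2, 0.3),
                           late = c(3, 3, 0.3)),
    gait_freq_hz = c(early = 1, middle = 0.8, late = 0.6),
    duration_range = c(30, 90))
  res <- purrr::map_df(1:10, function(s) {
    cohort <- generate_cohort(cfg, seed = 100 + s)
    feats <- extract_features(cohort)
    sp <- split_cohort(feats, 0.2, seed = 200 + s)
    tr <- split_side(feats, sp, "train")
    te <- split_side(feats, sp, "test")
    m <- train_nn(tr, hidden = 30, seed = 300 + s, max_iter = 300)
    b <- stage_baselines(feats, sp, seed = 400 + s)
    tibble::tibble(nn = glance(classify_patients(m, te))$success_rate,
                   tree = glance(b$tree)$success_rate,
                   forest = glance(b$forest)$success_rate,
                   svm = glance(b$svm)$success_rate)
  })
  means <- colMeans(res)
  expect_gte(means[["nn"]], means[["tree"]])
  expect_gte(means[["nn"]], means[["forest"]])
  expect_gte(means[["nn"]], means[["svm"]])
})
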