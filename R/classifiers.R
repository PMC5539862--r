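#' Patient-grouped train/test split
#'
#' Splits the cohort's recordings into training and test sides so that every
#' recording of a patient falls on that patient's side. Patients are
#' shuffled and a prefix is assigned to the test side, choosing the prefix
#' whose recording count is closest to the target fraction. Seeds are
#' retried (deterministically derived from `seed`) until every stage is
#' present in the training side.
#'
#' @param features Tibble with one row per recording and columns
#'   `patient_id`, `stage` (a feature table from [extract_features()], or a
#'   cohort).
#' @param test_fraction Target fraction of recordings on the test side;
#'   0 puts every patient in training.
#' @param seed Integer seed.
#' @param max_retries Seed retries before giving up.
#' @return An `sw_split`: list with `train_patients`, `test_patients`, the
#'   per-stage `counts` table (patients and recordings on each side), and
#'   the seed used.
#' @export
split_cohort <- function(features, test_fraction = 0.2, seed = NULL,
                         max_retries = 100) {
  if (test_fraction < 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie in [0, 1)")
  }
  pat <- features %>%
    group_by(patient_id = .data$patient_id) %>%
    summarise(stage = .data$stage[1], n_rec = dplyr::n(), .groups = "drop")
  total <- sum(pat$n_rec)
  for (try in seq_len(max_retries)) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, try - 1L)
    perm <- with_seed_if(s, sample.int(nrow(pat)))
    cum <- c(0, cumsum(pat$n_rec[perm]))
    k <- which.min(abs(cum / total - test_fraction)) - 1L
    test_p <- pat$patient_id[perm[seq_len(k)]]
    train_p <- setdiff(pat$patient_id, test_p)
    train_stages <- pat$stage[pat$patient_id %in% train_p]
    if (all(stage_levels() %in% as.character(train_stages))) {
      counts <- pat %>%
        mutate(side = ifelse(.data$patient_id %in% test_p, "test", "train")) %>%
        group_by(side = .data$side, stage = as_stage(.data$stage)) %>%
        summarise(patients = dplyr::n(), recordings = sum(.data$n_rec),
                  .groups = "drop") %>%
        tidyr::complete(side = c("train", "test"),
                        stage = as_stage(stage_levels()),
                        fill = list(patients = 0L, recordings = 0L))
      return(structure(list(train_patients = train_p,
                            test_patients = test_p,
                            counts = counts,
                            test_fraction = test_fraction,
                            seed = seed, seed_used = s),
                       class = "sw_split"))
    }
    if (is.null(seed)) next
  }
  abort("could not find a split with every stage in training")
}

#' @export
print.sw_split <- function(x, ...) {
  cat(sprintf("<sw_split> %d training / %d test patients\n",
              length(x$train_patients), length(x$test_patients)))
  print(as.data.frame(x$counts), row.names = FALSE)
  invisible(x)
}

#' Select one side of a patient-grouped split
#'
#' @param features Tibble with a `patient_id` column (one row per recording).
#' @param split An [split_cohort()] result.
#' @param side `"train"` or `"test"`.
#' @return The rows of `features` belonging to that side's patients.
#' @export
split_side <- function(features, split, side = c("train", "test")) {
  side <- match.arg(side)
  ids <- if (side == "train") split$train_patients else split$test_patients
  features[features$patient_id %in% ids, , drop = FALSE]
}

#' Patient-level classification report from recording predictions
#'
#' Classifies each test recording with the fitted model, assigns each test
#' patient the majority stage over their recordings (ties resolved toward
#' the stage most prevalent in training, then the fixed stage order), and
#' tabulates per-stage misclassifications and success rates.
#'
#' @param model A fitted model with a `predict` method returning stages
#'   (an `sw_mlp`, or one of the baseline fits).
#' @param features Test feature tibble (all rows must carry `patient_id`).
#' @param method Label used in the report.
#' @return An `sw_report`.
#' @export
classify_patients <- function(model, features, method = class(model)[1]) {
  if (anyNA(features$patient_id)) abort("every recording needs a patient_id")
  pred <- predict_stages(model, features)
  prevalence <- model_prevalence(model)
  patients <- tibble(patient_id = features$patient_id,
                     stage = as_stage(features$stage),
                     predicted = pred) %>%
    group_by(.data$patient_id) %>%
    summarise(stage = .data$stage[1],
              predicted = majority_vote(.data$predicted, prevalence),
              .groups = "drop")
  make_report(patients, method)
}

predict_stages <- function(model, features) UseMethod("predict_stages")

#' @export
predict_stages.sw_mlp <- function(model, features) {
  predict(model, features, type = "stage")
}

#' @export
predict_stages.sw_baseline <- function(model, features) {
  x <- as.data.frame(scale_features(features, model$center, model$scale))
  p <- switch(model$kind,
              tree = predict(model$fit, x, type = "class"),
              forest = predict(model$fit, x),
              svm = predict(model$fit, x))
  factor(as.character(p), levels = stage_levels())
}

model_prevalence <- function(model) {
  if (!is.null(model$prevalence)) model$prevalence else NULL
}

scale_features <- function(features, center, scale) {
  x <- as.matrix(features[, names(center)])
  sweep(sweep(x, 2, center), 2, scale, "/")
}

#' Baseline multivariate classifiers (tree, random forest, SVM)
#'
#' Trains the three reference classifiers on the standardised training
#' features of a patient-grouped split and reports patient-level
#' majority-vote performance on the test side, in the same report layout as
#' the neural network.
#'
#' @param features Feature tibble for the full cohort.
#' @param split An [split_cohort()] result.
#' @param seed Integer seed (forest and any randomised fit).
#' @return Named list of `sw_report`s: `tree`, `forest`, `svm`.
#' @export
stage_baselines <- function(features, split, seed = NULL) {
  train <- split_side(features, split, "train")
  test <- split_side(features, split, "test")
  if (nrow(test) == 0) abort("empty test side")
  cols <- feature_columns(train)
  x <- as.matrix(train[, cols])
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- as.data.frame(sweep(sweep(x, 2, center), 2, scl, "/"))
  df <- cbind(stage = as_stage(train$stage), xs)
  prevalence <- table(as_stage(train$stage)) / nrow(train)
  if (all(apply(x, 2, sd) == 0)) {
    # fully degenerate features: every method reduces to the majority class
    maj <- as.character(majority_vote(train$stage, prevalence))
    return(purrr::map(
      setNames(c("tree", "forest", "svm"), c("tree", "forest", "svm")),
      function(kind) {
        patients <- test %>%
          group_by(.data$patient_id) %>%
          summarise(stage = .data$stage[1], .groups = "drop") %>%
          mutate(predicted = maj)
        make_report(patients, kind)
      }))
  }
  fits <- with_seed_if(seed, list(
    tree = rpart::rpart(stage ~ ., data = df, method = "class"),
    forest = randomForest::randomForest(stage ~ ., data = df),
    svm = e1071::svm(stage ~ ., data = df)
  ))
  purrr::imap(fits, function(fit, kind) {
    model <- structure(list(fit = fit, kind = kind, center = center,
                            scale = scl, prevalence = prevalence),
                       class = "sw_baseline")
    classify_patients(model, test, method = kind)
  })
}

#' Misclassification sweep over network depths
#'
#' For each layer setting d, trains `n_networks` networks whose roughly 175
#' hidden neurons are spread over d hidden layers, each from a different
#' derived seed, and records the patient-level misclassification rate on the
#' test side of the split.
#'
#' @param features Feature tibble for the full cohort.
#' @param split An [split_cohort()] result.
#' @param layers Integer vector of hidden-layer depths to sweep.
#' @param n_networks Networks per setting.
#' @param hidden_total Total hidden neurons divided across the layers.
#' @param seed Master seed.
#' @param ... Passed to [train_nn()] (e.g. `max_iter`).
#' @return An `sw_sweep` tibble with columns `layers`, `network`,
#'   `misclassification`; boxplot-ready (see [autoplot.sw_sweep()]).
#' @export
layer_sweep <- function(features, split, layers = 1:11, n_networks = 100,
                        hidden_total = 175, seed = NULL, ...) {
  train <- split_side(features, split, "train")
  test <- split_side(features, split, "test")
  if (nrow(test) == 0) abort("empty test side")
  rows <- purrr::map(layers, function(d) {
    sizes <- diff(round(seq(0, hidden_total, length.out = d + 1)))
    sizes[sizes < 1] <- 1
    rates <- vapply(seq_len(n_networks), function(b) {
      s <- if (is.null(seed)) NULL else derive_seed(seed, d * 100000L + b)
      model <- train_nn(train, hidden = sizes, seed = s, ...)
      rep_ <- classify_patients(model, test, method = "nn")
      total <- rep_$by_stage[rep_$by_stage$stage == "total", ]
      total$misclassified / total$n
    }, numeric(1))
    tibble(layers = d, network = seq_len(n_networks),
           misclassification = rates)
  })
  out <- bind_rows(rows)
  class(out) <- c("sw_sweep", class(out))
  out
}
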