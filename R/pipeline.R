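#' Configuration of a full synthetic study
#'
#' Bundles every stage's settings: cohort generation, which axes the
#' mean-equality tests run on, test repetitions and bootstrap sizes, the
#' depth classifier, feature extraction, the patient-grouped split, the
#' neural network, and the depth sweep. A master seed is mandatory; every
#' stage derives its own stream from it, so stages are individually
#' reproducible.
#'
#' @param cohort A [cohort_config()] (or a list of its arguments).
#' @param seed Master seed (required).
#' @param axes Axes for the mean-equality tests.
#' @param n_reps_tests Windowing repetitions J for the test summaries.
#' @param B Bootstrap samples for the bootstrap tests.
#' @param k Random projections for the projection ANOVA.
#' @param depth_axes Axis sets for the depth classifier.
#' @param depth_reps Windowing repetitions for the depth classifier.
#' @param feature_mode `"basic90"` or `"extended"`.
#' @param test_fraction Recording-level test fraction of the split.
#' @param nn_hidden Hidden layout of the reported network.
#' @param nn_max_iter Maximum rprop+ iterations.
#' @param sweep_layers Depths swept (set to `integer(0)` to skip the sweep).
#' @param sweep_networks Networks per swept depth.
#' @param hidden_total Total hidden neurons in swept networks.
#' @return A list with class `sw_study_config`.
#' @export
study_config <- function(cohort = cohort_config(), seed = NULL,
                         axes = c("x", "y", "z"), n_reps_tests = 1000,
                         B = 999, k = 30,
                         depth_axes = c("x", "y", "xyz"), depth_reps = 10,
                         feature_mode = "basic90", test_fraction = 0.2,
                         nn_hidden = 175, nn_max_iter = 1000,
                         sweep_layers = 1:11, sweep_networks = 100,
                         hidden_total = 175) {
  if (is.null(seed)) abort("`seed` is required: no unseeded runs")
  if (is.list(cohort) && !inherits(cohort, "sw_cohort_config")) {
    cohort <- do.call(cohort_config, cohort)
  }
  stopifnot(inherits(cohort, "sw_cohort_config"))
  if (!all(axes %in% c("x", "y", "z"))) abort("axes must be x, y or z")
  if (!all(depth_axes %in% c("x", "y", "xyz"))) {
    abort("depth_axes must be among x, y, xyz")
  }
  check_number(n_reps_tests, "n_reps_tests", 1)
  check_number(B, "B", 1)
  check_number(k, "k", 1)
  structure(list(cohort = cohort, seed = as.integer(seed), axes = axes,
                 n_reps_tests = n_reps_tests, B = B, k = k,
                 depth_axes = depth_axes, depth_reps = depth_reps,
                 feature_mode = feature_mode, test_fraction = test_fraction,
                 nn_hidden = nn_hidden, nn_max_iter = nn_max_iter,
                 sweep_layers = sweep_layers, sweep_networks = sweep_networks,
                 hidden_total = hidden_total),
            class = "sw_study_config")
}

#' Read a study configuration from YAML
#'
#' The YAML keys mirror the arguments of [study_config()]; the `cohort` key,
#' if present, holds [cohort_config()] arguments (matrix-valued arguments as
#' per-stage named lists of x/y/z values).
#'
#' @param path Path to the YAML file.
#' @return An `sw_study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cohort)) {
    cc <- raw$cohort
    for (f in c("stage_shift", "gait_amplitude")) {
      if (!is.null(cc[[f]])) {
        cc[[f]] <- do.call(rbind, lapply(cc[[f]], unlist))[stage_levels(), ,
                                                           drop = FALSE]
      }
    }
    for (f in c("n_patients", "gait_freq_hz", "duration_range")) {
      if (!is.null(cc[[f]])) cc[[f]] <- unlist(cc[[f]])
    }
    if (!is.null(cc$recordings_per_patient)) {
      cc$recordings_per_patient <- lapply(cc$recordings_per_patient, unlist)
    }
    if (!is.null(cc$n_patients)) {
      cc$n_patients <- setNames(as.integer(cc$n_patients),
                                names(cc$n_patients))
    }
    raw$cohort <- do.call(cohort_config, cc)
  }
  for (f in c("axes", "depth_axes", "sweep_layers", "nn_hidden")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(study_config, raw)
}

write_stamped_csv <- function(df, path, seed, config_hash) {
  df$seed <- seed
  df$config_hash <- config_hash
  readr::write_csv(df, path)
}

#' Run the full synthetic study end-to-end
#'
#' Generates the cohort, writes its log files, runs the repeated-windowing
#' mean-equality tests on each configured axis, evaluates the depth
#' classifier leave-one-patient-out, extracts features, performs the
#' patient-grouped split, trains and evaluates the neural network and the
#' baseline classifiers, optionally sweeps network depths, and writes every
#' table as CSV (each stamped with the master seed and a config hash) plus a
#' machine-readable JSON run manifest. Rerunning with the same config
#' reproduces all outputs except the timings in the manifest.
#'
#' @param config An [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_study <- function(config, out_dir) {
  stopifnot(inherits(config, "sw_study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  chash <- rlang::hash(config)
  timings <- list()
  tick <- function(name, code) {
    t0 <- Sys.time()
    res <- code
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  cohort <- tick("simulate", {
    ch <- generate_cohort(config$cohort, seed = derive_seed(seed, 1))
    write_cohort(ch, file.path(out_dir, "cohort"))
    ch
  })
  curves <- interpolate_to_seconds(cohort)

  test_rows <- tick("tests", {
    pairs <- list(c("early", "middle"), c("early", "late"),
                  c("middle", "late"))
    purrr::imap(setNames(config$axes, config$axes), function(ax, i) {
      base <- derive_seed(seed, 1000 + 10 * match(ax, c("x", "y", "z")))
      rows <- list(
        tidy(repeated_test(curves, ax, "rp-bonf", config$n_reps_tests,
                           derive_seed(base, 1), k = config$k)),
        tidy(repeated_test(curves, ax, "rp-fdr", config$n_reps_tests,
                           derive_seed(base, 2), k = config$k)),
        tidy(repeated_test(curves, ax, "maxf", config$n_reps_tests,
                           derive_seed(base, 3), B = config$B))
      )
      for (p in seq_along(pairs)) {
        rows[[3 + p]] <- tidy(repeated_test(
          curves, ax, "l2", config$n_reps_tests,
          derive_seed(base, 3 + p), stages = pairs[[p]], B = config$B))
      }
      bind_rows(rows)
    }) %>% bind_rows()
  })
  write_stamped_csv(test_rows, file.path(out_dir, "test_summaries.csv"),
                    seed, chash)

  depth_rows <- tick("depth", {
    purrr::map(config$depth_axes, function(ax) {
      rep_ <- lopo_evaluate(cohort, axis = ax, n_reps = config$depth_reps,
                            seed = derive_seed(seed, 2000 + nchar(ax)))
      mutate(tidy(rep_), axis = ax, .before = 1)
    }) %>% bind_rows()
  })
  write_stamped_csv(depth_rows, file.path(out_dir, "depth_report.csv"),
                    seed, chash)

  features <- tick("features", extract_features(cohort, config$feature_mode))
  readr::write_csv(features %>% select(-dplyr::any_of("data")),
                   file.path(out_dir, "features.csv"))

  split <- split_cohort(features, config$test_fraction,
                        seed = derive_seed(seed, 3000))
  write_stamped_csv(tidy(split), file.path(out_dir, "split.csv"),
                    seed, chash)

  class_rows <- tick("classify", {
    model <- train_nn(split_side(features, split, "train"),
                      hidden = config$nn_hidden,
                      seed = derive_seed(seed, 4000),
                      max_iter = config$nn_max_iter)
    nn_rep <- classify_patients(model, split_side(features, split, "test"),
                                method = "nn")
    base <- stage_baselines(features, split, seed = derive_seed(seed, 5000))
    bind_rows(c(list(nn = nn_rep), base) %>% purrr::map(tidy))
  })
  write_stamped_csv(class_rows, file.path(out_dir, "classification.csv"),
                    seed, chash)

  if (length(config$sweep_layers) > 0) {
    sweep <- tick("sweep", {
      layer_sweep(features, split, layers = config$sweep_layers,
                  n_networks = config$sweep_networks,
                  hidden_total = config$hidden_total,
                  seed = derive_seed(seed, 6000),
                  max_iter = config$nn_max_iter)
    })
    write_stamped_csv(as_tibble(sweep), file.path(out_dir, "sweep.csv"),
                      seed, chash)
  }

  manifest <- list(
    package = "stagewalk",
    version = as.character(utils::packageVersion("stagewalk")),
    r_version = R.version.string,
    seed = seed,
    config_hash = chash,
    timings_sec = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
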