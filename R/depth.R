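# L2 distance between curves on the unit-spaced grid, trapezoidal quadrature.
l2_curve_dist <- function(f, g) {
  sqrt(trapz_grid((f - g)^2))
}

# All pairwise L2 (trapezoidal) distances between the rows of a
# curves-by-grid matrix, via the weighted Gram matrix.
curve_dist_matrix <- function(mat) {
  w <- trapz_weights(ncol(mat))
  gram <- sweep(mat, 2, w, "*") %*% t(mat)
  q <- diag(gram)
  d2 <- outer(q, q, "+") - 2 * gram
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' h-mode depth of a curve with respect to a reference sample
#'
#' The h-mode depth of a curve f with respect to a sample \{x_1, ..., x_m\}
#' is the average kernel-transformed distance `mean(K(d(f, x_i) / h))`, with
#' K the standard Gaussian kernel and d the L2 distance on the grid
#' (trapezoidal quadrature). It is largest near the mode of the sample's
#' distribution and decays to zero far from it.
#'
#' @param curve Numeric vector on the common grid.
#' @param reference Curves-by-grid matrix of reference curves (non-empty).
#' @param h Positive bandwidth. See [hmode_bandwidth()] for the default used
#'   by the classifier.
#' @return The depth, a value in `(0, dnorm(0)]`.
#' @export
hmode_depth <- function(curve, reference, h) {
  if (!is.matrix(reference)) reference <- matrix(reference, nrow = 1)
  if (nrow(reference) < 1) abort("reference group must be non-empty")
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0) {
    abort("`h` must be a positive number")
  }
  d <- vapply(seq_len(nrow(reference)),
              function(i) l2_curve_dist(curve, reference[i, ]), numeric(1))
  mean(dnorm(d / h))
}

#' Depth bandwidth: a quantile of within-sample distances
#'
#' The classifier sets the h-mode bandwidth of each reference group to the
#' 15th percentile of the pairwise L2 distances within that group, a common
#' convention for mode depths. Degenerate groups (all curves identical, or a
#' single curve) fall back to a small positive bandwidth.
#'
#' @param reference Curves-by-grid matrix.
#' @param prob Quantile level of the pairwise distances.
#' @return A positive bandwidth.
#' @export
hmode_bandwidth <- function(reference, prob = 0.15) {
  if (!is.matrix(reference)) reference <- matrix(reference, nrow = 1)
  m <- nrow(reference)
  if (m < 2) return(1)
  d <- curve_dist_matrix(reference)
  h <- quantile(d[upper.tri(d)], prob, names = FALSE)
  max(h, 1e-8)
}

#' Reduce curves to the three-dimensional depth space
#'
#' Computes the h-mode depth of each curve with respect to each of the three
#' stage training groups, so every functional datum becomes a point in R^3
#' (depth versus early, middle, late).
#'
#' @param windows Curves to transform: one repetition of an `sw_windows`
#'   tibble, or a curves-by-grid matrix.
#' @param training One repetition of an `sw_windows` tibble holding the
#'   training curves with their `stage` labels (all three stages present).
#' @param h Optional named numeric of per-group bandwidths; defaults to
#'   [hmode_bandwidth()] per group.
#' @return A tibble with columns `depth_early`, `depth_middle`, `depth_late`.
#' @export
depth_transform <- function(windows, training, h = NULL) {
  mat <- if (is.matrix(windows)) windows else windows_matrix(windows)
  tmat <- windows_matrix(training)
  stage <- droplevels(as_stage(training$stage))
  if (!all(stage_levels() %in% levels(stage))) {
    abort("all three stage groups must be present in `training`")
  }
  depths <- purrr::map(stage_levels(), function(s) {
    ref <- tmat[stage == s, , drop = FALSE]
    hg <- if (is.null(h)) hmode_bandwidth(ref) else h[[s]]
    vapply(seq_len(nrow(mat)),
           function(i) hmode_depth(mat[i, ], ref, hg), numeric(1))
  })
  out <- tibble(depth_early = depths[[1]], depth_middle = depths[[2]],
                depth_late = depths[[3]])
  out
}

# Isotropic Scott bandwidth for a points-by-dims matrix.
scott_bandwidth <- function(x) {
  n <- nrow(x)
  d <- ncol(x)
  bw <- mean(apply(x, 2, sd)) * n^(-1 / (d + 4))
  if (!is.finite(bw) || bw <= 0) bw <- 1e-8
  bw
}

#' Nadaraya-Watson kernel classifier in depth space
#'
#' Estimates each stage's class-conditional density at a query point by a
#' Gaussian kernel density estimate (Euclidean norm, isotropic bandwidth)
#' over that stage's training points, and predicts the stage maximising
#' density times the empirical class prior. Exact score ties are resolved
#' toward the stage with the largest training prevalence, then by the fixed
#' stage order early < middle < late.
#'
#' @param x Query points: numeric vector (one point) or points-by-dims matrix.
#' @param training Points-by-dims matrix of training points.
#' @param labels Stage labels of the training points.
#' @param bandwidth Positive kernel bandwidth; default is Scott's rule on the
#'   training points.
#' @return Factor of predicted stages, one per query point.
#' @export
nw_classify <- function(x, training, labels, bandwidth = NULL) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  training <- as.matrix(training)
  labels <- droplevels(as_stage(labels))
  if (!all(stage_levels() %in% levels(labels))) {
    abort("training set must contain all three stages")
  }
  bw <- bandwidth %||% scott_bandwidth(training)
  if (!is.numeric(bw) || bw <= 0) abort("`bandwidth` must be positive")
  prior <- table(labels) / length(labels)
  d <- ncol(training)
  norm_const <- (2 * pi)^(-d / 2) * bw^(-d)
  scores <- vapply(stage_levels(), function(s) {
    pts <- training[labels == s, , drop = FALSE]
    vapply(seq_len(nrow(x)), function(i) {
      d2 <- rowSums(sweep(pts, 2, x[i, ])^2)
      prior[[s]] * norm_const * mean(exp(-d2 / (2 * bw^2)))
    }, numeric(1))
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x),
                   dimnames = list(NULL, stage_levels()))
  prev <- prior
  preds <- apply(scores, 1, function(sc) {
    top <- stage_levels()[sc == max(sc)]
    if (length(top) > 1) {
      pv <- prev[top]
      top <- top[pv == max(pv)]
    }
    top[1]
  })
  factor(preds, levels = stage_levels())
}

make_report <- function(patients, method) {
  patients <- dplyr::mutate(patients,
                            stage = as_stage(.data$stage),
                            predicted = as_stage(.data$predicted))
  by_stage <- patients %>%
    group_by(stage = .data$stage) %>%
    summarise(n = dplyr::n(),
              misclassified = sum(.data$predicted != .data$stage),
              .groups = "drop") %>%
    tidyr::complete(stage = as_stage(stage_levels()),
                    fill = list(n = 0L, misclassified = 0L)) %>%
    mutate(success_rate = ifelse(.data$n > 0,
                                 (.data$n - .data$misclassified) / .data$n,
                                 NA_real_))
  total <- tibble(stage = "total",
                  n = sum(by_stage$n),
                  misclassified = sum(by_stage$misclassified),
                  success_rate = 1 - sum(by_stage$misclassified) /
                    sum(by_stage$n))
  by_stage$stage <- as.character(by_stage$stage)
  structure(list(by_stage = bind_rows(by_stage, total),
                 patients = patients, method = method),
            class = "sw_report")
}

#' @export
print.sw_report <- function(x, ...) {
  cat(sprintf("<sw_report> %s\n", x$method))
  print(as.data.frame(x$by_stage), row.names = FALSE)
  invisible(x)
}

#' Leave-one-patient-out evaluation of the depth classifier
#'
#' For each repetition, draws fresh random windows, reduces every curve to
#' its three-group depth vector, and classifies each held-out patient's
#' curves with the Nadaraya-Watson rule trained on the remaining patients'
#' depth vectors. A patient's per-repetition label is the majority over their
#' curves; the final label is the majority over repetitions. The held-out
#' patient's curves never enter the reference groups, the bandwidths, or the
#' kernel classifier's training set.
#'
#' @param cohort An `sw_cohort` tibble.
#' @param axis `"x"`, `"y"`, or `"xyz"` (per-axis windows concatenated).
#' @param n_reps Number of windowing repetitions.
#' @param seed Master seed.
#' @param h_prob Quantile level for the per-group depth bandwidth.
#' @return An `sw_report` with per-stage misclassification counts and success
#'   rates plus the per-patient predictions.
#' @export
lopo_evaluate <- function(cohort, axis = c("x", "y", "xyz"), n_reps = 10,
                          seed = NULL, h_prob = 0.15) {
  axis <- match.arg(axis)
  curves <- interpolate_to_seconds(cohort)
  pat <- curves %>% distinct(.data$patient_id, .data$stage)
  if (any(table(as_stage(pat$stage)) < 2)) {
    abort("leave-one-patient-out needs at least 2 patients per stage")
  }
  votes <- matrix(NA_character_, nrow = nrow(pat), ncol = n_reps)
  for (j in seq_len(n_reps)) {
    w <- random_windows(curves, axis = if (axis == "xyz") "xyz" else axis,
                        n_reps = 1,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, j))
    mat <- windows_matrix(w)
    D <- curve_dist_matrix(mat)
    stage <- as_stage(w$stage)
    for (p in seq_len(nrow(pat))) {
      test_idx <- which(w$patient_id == pat$patient_id[p])
      train_idx <- setdiff(seq_len(nrow(w)), test_idx)
      train_stage <- droplevels(stage[train_idx])
      # depth vectors from the precomputed distance matrix
      depth_cols <- purrr::map(stage_levels(), function(s) {
        gidx <- train_idx[train_stage == s]
        dsub <- D[gidx, gidx, drop = FALSE]
        hg <- if (length(gidx) >= 2) {
          max(quantile(dsub[upper.tri(dsub)], h_prob, names = FALSE), 1e-8)
        } else 1
        rowMeans(dnorm(D[, gidx, drop = FALSE] / hg))
      })
      dv <- do.call(cbind, depth_cols)
      prevalence <- table(train_stage) / length(train_idx)
      pred <- nw_classify(dv[test_idx, , drop = FALSE],
                          dv[train_idx, , drop = FALSE],
                          stage[train_idx])
      votes[p, j] <- as.character(majority_vote(pred, prevalence))
    }
  }
  prevalence_all <- table(as_stage(pat$stage))
  final <- vapply(seq_len(nrow(pat)), function(p) {
    as.character(majority_vote(votes[p, ], prevalence_all))
  }, character(1))
  make_report(tibble(patient_id = pat$patient_id, stage = pat$stage,
                     predicted = final),
              sprintf("h-mode depth + Nadaraya-Watson, %s-axis, %d reps",
                      axis, n_reps))
}
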