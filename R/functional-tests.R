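new_sw_test <- function(p_value, statistic, method, parameters, seed = NULL) {
  structure(list(p_value = p_value, statistic = statistic, method = method,
                 parameters = parameters, seed = seed),
            class = "sw_test")
}

#' @export
print.sw_test <- function(x, ...) {
  cat(sprintf("<sw_test> %s\n  statistic = %.6g, p-value = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

split_groups <- function(mat, stage) {
  stage <- droplevels(as_stage(stage))
  lapply(levels(stage), function(s) mat[stage == s, , drop = FALSE])
}

# Pointwise one-way ANOVA F statistic across the grid for a list of
# curves-by-grid matrices. Zero within-group variance at some grid point is
# guarded by a machine-epsilon-scaled ridge on the denominator (warning);
# zero everywhere is an error.
pointwise_F <- function(groups) {
  G <- length(groups)
  ns <- vapply(groups, nrow, integer(1))
  N <- sum(ns)
  means <- lapply(groups, colMeans)
  ssq <- lapply(groups, function(m) colSums(m^2))
  grand <- Reduce(`+`, purrr::map2(means, ns, `*`)) / N
  between <- Reduce(`+`, purrr::map2(means, ns, function(m, n) {
    n * (m - grand)^2
  })) / (G - 1)
  within_ss <- Reduce(`+`, purrr::map2(ssq, seq_along(groups), function(s, i) {
    s - ns[i] * means[[i]]^2
  }))
  within <- within_ss / (N - G)
  within[within < 0] <- 0 # numerical round-off
  if (all(within == 0)) {
    abort("zero within-group variance at every grid point")
  }
  if (any(within == 0)) {
    ridge <- .Machine$double.eps * max(between, 1)
    within <- within + ridge
    warn("zero within-group variance at some grid points; ridge applied")
  }
  between / within
}

#' Random projections of functional data onto the unit sphere
#'
#' Draws k directions uniformly on the unit sphere of the grid space (a
#' standard normal vector normalised to unit Euclidean norm) and projects
#' every curve onto each direction by the inner product.
#'
#' @param windows One repetition of an [random_windows()] tibble, or a
#'   curves-by-grid matrix.
#' @param k Number of projections.
#' @param seed Integer seed for the directions.
#' @return A list with `projections` (n x k matrix) and `directions`
#'   (l x k matrix of unit vectors).
#' @export
random_projections <- function(windows, k = 30, seed = NULL) {
  mat <- if (is.matrix(windows)) windows else windows_matrix(windows)
  l <- ncol(mat)
  if (l < 1) abort("curves must have at least one grid point")
  if (k < 1) abort("`k` must be at least 1")
  dirs <- with_seed_if(seed, {
    d <- matrix(rnorm(l * k), nrow = l, ncol = k)
    sweep(d, 2, sqrt(colSums(d^2)), "/")
  })
  list(projections = mat %*% dirs, directions = dirs)
}

#' Functional ANOVA by random projections
#'
#' Tests equality of the three stage mean curves by projecting the curves
#' onto k random directions on the unit sphere, applying the classical
#' one-way ANOVA F test (equal variances; parametric) to each projection and
#' combining the k p-values with either the Bonferroni correction
#' (p = min(1, k min p)) or the Benjamini-Hochberg FDR (p = min of the
#' BH-adjusted p-values).
#'
#' @param windows One repetition of a windowed dataset containing three
#'   non-empty stage groups (an `sw_windows` tibble).
#' @param k Number of random projections.
#' @param combine `"bonferroni"` or `"fdr"`.
#' @param seed Integer seed for the projection directions.
#' @return An `sw_test` object; `statistic` is the minimum raw projection
#'   p-value.
#' @export
anova_rp <- function(windows, k = 30, combine = c("bonferroni", "fdr"),
                     seed = NULL) {
  combine <- match.arg(combine)
  mat <- windows_matrix(windows)
  stage <- droplevels(as_stage(windows$stage))
  if (nlevels(stage) != 3) abort("three non-empty stage groups are required")
  if (any(table(stage) < 2)) {
    abort("every group needs at least 2 curves for the F test")
  }
  pr <- random_projections(mat, k = k, seed = seed)$projections
  pvals <- vapply(seq_len(k), function(j) {
    v <- pr[, j]
    wv <- tapply(v, stage, var)
    if (any(wv == 0)) {
      abort(paste0("zero within-group variance on projection ", j))
    }
    oneway.test(v ~ stage, var.equal = TRUE)$p.value
  }, numeric(1))
  p <- if (combine == "bonferroni") {
    min(1, k * min(pvals))
  } else {
    min(p.adjust(pvals, method = "BH"))
  }
  new_sw_test(p, min(pvals),
              paste0("random-projection ANOVA (", combine, ")"),
              list(k = k, combine = combine, projection_p = pvals), seed)
}

#' Bootstrap functional ANOVA based on the maximum F statistic
#'
#' The test statistic is the supremum over the grid of the pointwise one-way
#' F statistic for the three stage groups. Its null distribution is emulated
#' by resampling curves with replacement within each group independently and
#' centering every bootstrap group by its original sample mean curve; the
#' p-value is (1 + #\{bootstrap T >= observed T\})/(B + 1).
#'
#' @param windows One repetition of a windowed dataset with three groups.
#' @param B Number of bootstrap samples.
#' @param seed Integer seed for the resampling.
#' @return An `sw_test` object.
#' @export
anova_maxf <- function(windows, B = 999, seed = NULL) {
  mat <- windows_matrix(windows)
  stage <- droplevels(as_stage(windows$stage))
  if (nlevels(stage) != 3) abort("three non-empty stage groups are required")
  groups <- split_groups(mat, stage)
  if (any(vapply(groups, nrow, integer(1)) < 2)) {
    abort("every group needs at least 2 curves")
  }
  t_obs <- max(pointwise_F(groups))
  means <- lapply(groups, colMeans)
  t_boot <- with_seed_if(seed, {
    vapply(seq_len(B), function(b) {
      centered <- purrr::map2(groups, means, function(g, m) {
        idx <- sample.int(nrow(g), nrow(g), replace = TRUE)
        sweep(g[idx, , drop = FALSE], 2, m)
      })
      max(pointwise_F(centered))
    }, numeric(1))
  })
  p <- (1 + sum(t_boot >= t_obs)) / (B + 1)
  new_sw_test(p, t_obs, "bootstrap max-F ANOVA", list(B = B), seed)
}

#' Bootstrap two-sample test of equality of functional means (L2 norm)
#'
#' For two groups the statistic is the integrated (trapezoidal, unit-spaced
#' grid) squared difference of the sample mean curves. The null distribution
#' is emulated by resampling curves within each group and using the centered
#' bootstrap statistic, the integrated squared difference of the centered
#' bootstrap means; p = (1 + exceedances)/(B + 1).
#'
#' @param windows One repetition of a windowed dataset; it must contain the
#'   two stages named in `stages` (other rows are ignored).
#' @param stages Length-2 character: the two stage groups to compare.
#' @param B Number of bootstrap samples.
#' @param seed Integer seed.
#' @return An `sw_test` object.
#' @export
l2_mean_test <- function(windows, stages = c("early", "middle"), B = 999,
                         seed = NULL) {
  stopifnot(length(stages) == 2)
  stage <- as_stage(windows$stage)
  keep <- stage %in% stages
  mat <- windows_matrix(windows[keep, , drop = FALSE])
  g <- droplevels(stage[keep])
  if (nlevels(g) != 2 || any(table(g) < 2)) {
    abort("both groups need at least 2 curves")
  }
  gs <- split_groups(mat, g)
  m1 <- colMeans(gs[[1]]); m2 <- colMeans(gs[[2]])
  t_obs <- trapz_grid((m1 - m2)^2)
  t_boot <- with_seed_if(seed, {
    vapply(seq_len(B), function(b) {
      b1 <- colMeans(gs[[1]][sample.int(nrow(gs[[1]]), replace = TRUE), ,
                             drop = FALSE])
      b2 <- colMeans(gs[[2]][sample.int(nrow(gs[[2]]), replace = TRUE), ,
                             drop = FALSE])
      trapz_grid((b1 - m1 - b2 + m2)^2)
    }, numeric(1))
  })
  p <- (1 + sum(t_boot >= t_obs)) / (B + 1)
  new_sw_test(p, t_obs, paste0("bootstrap L2 mean test (",
                               paste(stages, collapse = " vs "), ")"),
              list(B = B, stages = stages), seed)
}

#' Summarise a mean-equality test over repeated random windowings
#'
#' Runs one of the functional tests on each of J windowed datasets (fresh
#' random offsets per repetition) and summarises the J p-values by their
#' mean, standard deviation, and the proportion smaller than or equal to
#' 0.05 — the row format of the repeated-windowing summary table.
#'
#' @param curves An `sw_curves` tibble from [interpolate_to_seconds()].
#' @param axis Axis to analyse (`"x"`, `"y"`, `"z"`, or `"xyz"`).
#' @param test One of `"rp-bonf"`, `"rp-fdr"`, `"maxf"`, `"l2"`.
#' @param n_reps Number of windowing repetitions J.
#' @param seed Master seed; windows and the inner test use derived streams.
#' @param stages For `test = "l2"` only: the two stages to compare.
#' @param B,k Bootstrap samples / number of projections for the inner test.
#' @return An `sw_pvalue_summary` object holding the raw p-values and the
#'   summary; see [tidy.sw_pvalue_summary()].
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' curves <- interpolate_to_seconds(cohort)
#' \donttest{
#' repeated_test(curves, axis = "x", test = "l2", n_reps = 20, seed = 2,
#'               stages = c("early", "middle"), B = 199)
#' }
#' @export
repeated_test <- function(curves, axis = c("x", "y", "z", "xyz"),
                          test = c("rp-bonf", "rp-fdr", "maxf", "l2"),
                          n_reps = 1000, seed = NULL,
                          stages = c("early", "middle"), B = 999, k = 30) {
  axis <- match.arg(axis)
  test <- match.arg(test)
  if (n_reps < 1) abort("`n_reps` must be at least 1")
  windows <- random_windows(curves, axis = axis, n_reps = n_reps, seed = seed)
  p_values <- vapply(seq_len(n_reps), function(j) {
    w <- windows[windows$rep == j, , drop = FALSE]
    sj <- if (is.null(seed)) NULL else derive_seed(seed, 100000 + j)
    res <- tryCatch(
      switch(test,
             "rp-bonf" = anova_rp(w, k = k, combine = "bonferroni", seed = sj),
             "rp-fdr"  = anova_rp(w, k = k, combine = "fdr", seed = sj),
             "maxf"    = anova_maxf(w, B = B, seed = sj),
             "l2"      = l2_mean_test(w, stages = stages, B = B, seed = sj)),
      error = function(e) {
        abort(paste0("repetition ", j, ": ", conditionMessage(e)))
      })
    res$p_value
  }, numeric(1))
  structure(list(
    p_values = p_values,
    mean = mean(p_values),
    sd = if (n_reps > 1) sd(p_values) else 0,
    prop_le_05 = mean(p_values <= 0.05),
    n_reps = n_reps, test = test, axis = axis,
    stages = if (test == "l2") stages else NULL,
    seed = seed
  ), class = "sw_pvalue_summary")
}

#' @export
print.sw_pvalue_summary <- function(x, ...) {
  cat(sprintf(
    "<sw_pvalue_summary> %s on %s-axis, J = %d\n  mean = %.4f, sd = %.4f, proportion <= 0.05 = %.3f\n",
    x$test, x$axis, x$n_reps, x$mean, x$sd, x$prop_le_05))
  invisible(x)
}
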