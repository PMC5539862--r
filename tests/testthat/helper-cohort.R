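# Small cohort configurations used across the suite. Effect levels scale the
# stage separation in the xy-plane; "none" is a true null (all stages share
# one process), "large" separates the stages far beyond the orientation
# noise.
test_config <- function(effect = c("none", "moderate", "large"),
                        n_per_stage = 4L, recs = 4L,
                        duration_range = c(60, 120)) {
  effect <- match.arg(effect)
  scale <- switch(effect, none = 0, moderate = 1, large = 2)
  cohort_config(
    n_patients = c(early = n_per_stage, middle = n_per_stage,
                   late = n_per_stage),
    recordings_per_patient = list(early = rep(recs, n_per_stage),
                                  middle = rep(recs, n_per_stage),
                                  late = rep(recs, n_per_stage)),
    duration_range = duration_range,
    stage_shift = rbind(early = c(0, 0, 0),
                        middle = scale * c(10, 9, 0.1),
                        late = scale * c(20, 18, 0.2)),
    gait_amplitude = rbind(early = c(1, 1, 0.3),
                           middle = c(1 + scale, 1 + scale, 0.3),
                           late = c(1 + 2 * scale, 1 + 2 * scale, 0.3)),
    gait_freq_hz = c(early = 1,
                     middle = if (scale > 0) 0.8 else 1,
                     late = if (scale > 0) 0.6 else 1)
  )
}

# Assemble a windowed-dataset tibble directly from a curves-by-grid matrix,
# bypassing the generator, for unit tests of the test statistics.
make_windows <- function(mat, stage) {
  out <- tibble::tibble(
    rep = 1L,
    recording_id = sprintf("r%d", seq_len(nrow(mat))),
    patient_id = sprintf("p%d", seq_len(nrow(mat))),
    stage = factor(stage, levels = stage_levels()),
    offset = 0L,
    values = lapply(seq_len(nrow(mat)), function(i) mat[i, ])
  )
  attr(out, "window_length") <- ncol(mat)
  out
}

# Gaussian null curves: iid N(0,1) plus a shared smooth component so the
# curves are not white noise.
null_curve_matrix <- function(n, l) {
  base <- sin(2 * pi * seq_len(l) / l)
  t(vapply(seq_len(n), function(i) {
    base * rnorm(1) + rnorm(l)
  }, numeric(l)))
}

# ---- independent brute-force oracles -------------------------------------

# pointwise one-way F via lm/anova at each grid point
bf_pointwise_F <- function(groups) {
  l <- ncol(groups[[1]])
  g <- factor(rep(seq_along(groups), vapply(groups, nrow, integer(1))))
  vapply(seq_len(l), function(t) {
    y <- unlist(lapply(groups, function(m) m[, t]))
    summary(stats::aov(y ~ g))[[1]]$`F value`[1]
  }, numeric(1))
}

bf_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

bf_l2_dist <- function(f, g) {
  sqrt(bf_trapz(seq_along(f), (f - g)^2))
}

bf_hmode_depth <- function(curve, ref, h) {
  vals <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    vals[i] <- stats::dnorm(bf_l2_dist(curve, ref[i, ]) / h)
  }
  mean(vals)
}

bf_nw_predict <- function(x, train, labels, bw) {
  labels <- factor(labels, levels = stage_levels())
  scores <- vapply(stage_levels(), function(s) {
    pts <- train[labels == s, , drop = FALSE]
    k <- numeric(nrow(pts))
    for (i in seq_len(nrow(pts))) {
      k[i] <- exp(-sum((x - pts[i, ])^2) / (2 * bw^2))
    }
    (nrow(pts) / nrow(train)) * (2 * pi)^(-ncol(train) / 2) * bw^(-ncol(train)) * mean(k)
  }, numeric(1))
  stage_levels()[which.max(scores)]
}

as_stage_helper <- function(x) factor(as.character(x), levels = stage_levels())
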