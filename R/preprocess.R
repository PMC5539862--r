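#' Interpolate recordings onto the integer-second grid
#'
#' Each irregularly sampled recording is linearly interpolated and evaluated
#' at t = 1, 2, ..., Ti seconds, where Ti is the rounded final timestamp
#' (round-half-to-even). Grid points outside the observed range take the
#' nearest observed value (constant extrapolation).
#'
#' @param cohort An `sw_cohort` tibble (or any tibble with the same columns).
#' @return A tibble with class `sw_curves`: one row per recording with columns
#'   `recording_id`, `patient_id`, `stage`, `t_end` (grid length Ti) and
#'   list-columns `x`, `y`, `z` of per-second values.
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' curves <- interpolate_to_seconds(cohort)
#' @export
interpolate_to_seconds <- function(cohort) {
  stopifnot(is.data.frame(cohort), "data" %in% names(cohort))
  one <- function(rec, id) {
    t_end <- round(rec$t[nrow(rec)])
    if (t_end < 2) {
      abort(paste0("recording ", id,
                   ": duration below 2 s, too short to interpolate"))
    }
    grid <- seq_len(t_end)
    vals <- lapply(c("ax", "ay", "az"), function(a) {
      approx(rec$t, rec[[a]], xout = grid, rule = 2)$y
    })
    list(t_end = t_end, x = vals[[1]], y = vals[[2]], z = vals[[3]])
  }
  res <- purrr::map2(cohort$data, cohort$recording_id, one)
  out <- tibble(
    recording_id = cohort$recording_id,
    patient_id = cohort$patient_id,
    stage = as_stage(cohort$stage),
    t_end = purrr::map_int(res, function(r) as.integer(r$t_end)),
    x = purrr::map(res, "x"),
    y = purrr::map(res, "y"),
    z = purrr::map(res, "z")
  )
  class(out) <- c("sw_curves", class(out))
  out
}

#' Equal-length datasets by random offset windows
#'
#' Recordings have different lengths Ti; because the within-recording process
#' is stationary, an equal-length dataset is obtained by taking from each
#' curve a window of length l = min(Ti) starting at a random offset li drawn
#' uniformly from {0, ..., Ti - l}. Offsets are redrawn independently per
#' curve and per repetition.
#'
#' @param curves An `sw_curves` tibble from [interpolate_to_seconds()].
#' @param axis One of `"x"`, `"y"`, `"z"`, or `"xyz"` (the three per-axis
#'   windows, sharing one offset, concatenated into a single vector).
#' @param n_reps Number of windowed datasets J to draw.
#' @param seed Integer master seed; repetition j uses a derived stream so
#'   changing `n_reps` never perturbs earlier repetitions.
#' @return A tibble with class `sw_windows`: columns `rep`, `recording_id`,
#'   `patient_id`, `stage`, `offset`, and list-column `values` (length l, or
#'   3l for `"xyz"`). The window length is in `attr(, "window_length")`.
#' @export
random_windows <- function(curves, axis = c("x", "y", "z", "xyz"),
                           n_reps = 1, seed = NULL) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(curves), nrow(curves) >= 2)
  l <- min(curves$t_end)
  if (l < 2) abort("window length below 2: degenerate input")
  axes <- if (axis == "xyz") c("x", "y", "z") else axis
  reps <- purrr::map(seq_len(n_reps), function(j) {
    offs <- with_seed_if(
      if (is.null(seed)) NULL else derive_seed(seed, j),
      purrr::map_int(curves$t_end, function(ti) {
        as.integer(sample.int(ti - l + 1L, 1L) - 1L)
      })
    )
    vals <- purrr::map2(seq_len(nrow(curves)), offs, function(i, li) {
      unlist(lapply(axes, function(a) curves[[a]][[i]][(1 + li):(l + li)]),
             use.names = FALSE)
    })
    tibble(rep = j,
           recording_id = curves$recording_id,
           patient_id = curves$patient_id,
           stage = curves$stage,
           offset = offs,
           values = vals)
  })
  out <- bind_rows(reps)
  attr(out, "window_length") <- l
  attr(out, "axis") <- axis
  class(out) <- c("sw_windows", class(out))
  out
}

# Stack one repetition of an sw_windows tibble into a curves-by-grid matrix.
windows_matrix <- function(windows) {
  do.call(rbind, windows$values)
}
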