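#' Configuration for the synthetic accelerometer cohort generator
#'
#' Describes a cohort of Alzheimer's patients carrying an Android smartphone
#' whose accelerometer logs three-axis accelerations at a nominal 8 Hz on an
#' irregular grid. Defaults reproduce the composition of the motivating case
#' study: 35 patients split 7 early / 18 middle / 10 late (by GDS grouping),
#' with a fixed per-patient recording schedule totalling 187 recordings
#' (41/100/46 by stage), each patient contributing between 2 and 8 recordings.
#'
#' The signal model for one recording is
#' `gravity projection + stage shift + gait sinusoid + AR(1) noise`,
#' per axis: a constant gravity component obtained by projecting 9.81 m/s^2
#' onto a random orientation drawn per recording (pocket placement varies
#' between recordings, even for one patient); a constant per-stage per-axis
#' mean shift; a sinusoidal gait component with stage-dependent amplitude and
#' frequency and a random phase per recording; and stationary AR(1) noise.
#' After the constant, the process is stationary, so equal-length windows
#' taken at random offsets are exchangeable in distribution. Stage effects
#' (shifts and gait amplitudes) are concentrated on the x and y axes — the
#' plane the patients move in — and are weak on z.
#'
#' @param n_patients Named integer vector: patients per stage.
#' @param recordings_per_patient Named list of integer vectors, one per stage,
#'   giving the (fixed) number of recordings of each patient of that stage.
#'   Each count must lie in 2..8.
#' @param rate_hz Nominal sampling rate in Hz.
#' @param duration_range Length-2 numeric, seconds; each recording's duration
#'   is drawn uniformly from this range.
#' @param stage_shift 3x3 numeric matrix (rows = stages, cols = x,y,z):
#'   constant mean acceleration shift per stage and axis, m/s^2.
#' @param gait_amplitude 3x3 numeric matrix: sinusoid amplitude per stage and
#'   axis, m/s^2.
#' @param gait_freq_hz Length-3 numeric: gait frequency per stage, Hz.
#' @param ar_phi,ar_sigma AR(1) noise parameters (lag-1 coefficient and
#'   innovation standard deviation, m/s^2).
#' @param gravity Gravity magnitude, m/s^2, split across axes by a random
#'   orientation per recording.
#' @param jitter Timestamp jitter as a fraction of the nominal sampling
#'   interval (uniform on `[0, 2 * jitter]` added to the regular grid, so
#'   consecutive gaps stay positive for `jitter < 0.5`).
#'
#' @return A list with class `sw_cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = c(early = 7L, middle = 18L, late = 10L),
                          recordings_per_patient = list(
                            early  = c(8L, 7L, 6L, 6L, 6L, 4L, 4L),
                            middle = c(rep(6L, 10), rep(5L, 8)),
                            late   = c(rep(5L, 6), rep(4L, 4))
                          ),
                          rate_hz = 8,
                          duration_range = c(120, 900),
                          stage_shift = rbind(
                            early  = c(x = 0,   y = 0,   z = 0),
                            middle = c(x = 0.6, y = 0.5, z = 0.08),
                            late   = c(x = 1.2, y = 1.0, z = 0.15)
                          ),
                          gait_amplitude = rbind(
                            early  = c(x = 1.0, y = 0.9, z = 0.30),
                            middle = c(x = 1.5, y = 1.3, z = 0.34),
                            late   = c(x = 2.0, y = 1.8, z = 0.38)
                          ),
                          gait_freq_hz = c(early = 1.0, middle = 0.8, late = 0.6),
                          ar_phi = 0.5,
                          ar_sigma = 0.5,
                          gravity = 9.81,
                          jitter = 0.2) {
  stages <- stage_levels()
  if (!all(stages %in% names(n_patients))) {
    abort("`n_patients` must be named with all of early/middle/late")
  }
  n_patients <- as.integer(n_patients[stages])
  if (any(n_patients <= 0)) abort("all stage patient counts must be positive")
  if (!all(stages %in% names(recordings_per_patient))) {
    abort("`recordings_per_patient` must have one entry per stage")
  }
  for (s in stages) {
    rp <- recordings_per_patient[[s]]
    if (length(rp) != n_patients[[match(s, stages)]]) {
      abort(paste0("recordings_per_patient$", s,
                   " must have one count per patient"))
    }
    if (any(rp < 2 | rp > 8)) {
      abort("recordings per patient must lie in 2..8")
    }
  }
  check_number(rate_hz, "rate_hz", 0, strict = TRUE)
  if (length(duration_range) != 2 || duration_range[1] <= 0 ||
      diff(duration_range) < 0) {
    abort("`duration_range` must be positive and non-decreasing")
  }
  check_number(ar_sigma, "ar_sigma", 0)
  check_number(gravity, "gravity", 0)
  if (abs(ar_phi) >= 1) abort("`ar_phi` must lie in (-1, 1)")
  if (jitter < 0 || jitter >= 0.5) abort("`jitter` must lie in [0, 0.5)")
  structure(list(
    n_patients = setNames(n_patients, stages),
    recordings_per_patient = recordings_per_patient[stages],
    rate_hz = rate_hz,
    duration_range = duration_range,
    stage_shift = stage_shift[stages, , drop = FALSE],
    gait_amplitude = gait_amplitude[stages, , drop = FALSE],
    gait_freq_hz = setNames(as.numeric(gait_freq_hz[stages]), stages),
    ar_phi = ar_phi, ar_sigma = ar_sigma,
    gravity = gravity, jitter = jitter
  ), class = "sw_cohort_config")
}

#' Theoretical stage mean functions of the generator
#'
#' The noiseless, orientation-averaged mean acceleration of each stage is
#' constant in time (gravity projection and gait phase average to zero), equal
#' to the configured stage shift. Useful for checking that the configured
#' between-stage separation lives in the xy-plane.
#'
#' @param config A [cohort_config()].
#' @return Tibble with columns `stage`, `axis`, `mean` (m/s^2).
#' @export
stage_mean_functions <- function(config) {
  stopifnot(inherits(config, "sw_cohort_config"))
  sh <- config$stage_shift
  tibble(
    stage = as_stage(rep(rownames(sh), each = 3)),
    axis = rep(c("x", "y", "z"), times = nrow(sh)),
    mean = as.numeric(t(sh))
  )
}

simulate_recording <- function(stage, config) {
  rate <- config$rate_hz
  dur <- runif(1, config$duration_range[1], config$duration_range[2])
  n <- floor(dur * rate) + 1L
  t <- (seq_len(n) - 1) / rate + runif(n, 0, 2 * config$jitter / rate)
  # random orientation of the device: unit vector uniform on the sphere
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  phase <- runif(1, 0, 2 * pi)
  freq <- config$gait_freq_hz[[stage]]
  out <- list(t = t)
  for (j in 1:3) {
    axis <- c("x", "y", "z")[j]
    gait <- config$gait_amplitude[stage, j] * sin(2 * pi * freq * t + phase)
    noise <- as.numeric(arima.sim(list(ar = config$ar_phi), n = n,
                                  sd = config$ar_sigma))
    out[[paste0("a", axis)]] <-
      config$gravity * u[j] + config$stage_shift[stage, j] + gait + noise
  }
  as_tibble(out)
}

#' Generate a synthetic cohort of accelerometer recordings
#'
#' Draws a full cohort under the signal model described in [cohort_config()].
#' Deterministic given `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; required for a reproducible cohort.
#' @return A tibble with class `sw_cohort`: one row per recording, columns
#'   `patient_id`, `stage`, `recording_id` and a list-column `data` of
#'   recording tibbles with columns `t` (seconds), `ax`, `ay`, `az` (m/s^2).
#'   The generating config and seed are attached as attributes.
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' dplyr::count(cohort, stage)
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "sw_cohort_config"))
  rows <- with_seed_if(seed, {
    purrr::map(stage_levels(), function(s) {
      counts <- config$recordings_per_patient[[s]]
      purrr::imap(counts, function(n_rec, i) {
        pid <- sprintf("%s_%02d", s, i)
        tibble(
          patient_id = pid,
          stage = s,
          recording_id = sprintf("%s_r%d", pid, seq_len(n_rec)),
          data = purrr::map(seq_len(n_rec),
                            function(k) simulate_recording(s, config))
        )
      }) %>% bind_rows()
    }) %>% bind_rows()
  })
  rows$stage <- as_stage(rows$stage)
  new_cohort(rows, config = config, seed = seed)
}

new_cohort <- function(x, config = NULL, seed = NULL) {
  out <- as_tibble(x)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("sw_cohort", class(out))
  out
}

#' Validate cohort and recording invariants
#'
#' Checks that every recording has >= 16 samples and strictly increasing
#' timestamps with a mean sampling interval within a factor 2 of the nominal
#' rate, that every patient has 2 to 8 recordings, and that all three stage
#' groups are non-empty.
#'
#' @param cohort An `sw_cohort` tibble.
#' @param rate_hz Nominal sampling rate used for the interval check.
#' @return `cohort`, invisibly; errors describe the first violation.
#' @export
validate_cohort <- function(cohort, rate_hz = 8) {
  stopifnot(is.data.frame(cohort))
  need <- c("patient_id", "stage", "recording_id", "data")
  if (!all(need %in% names(cohort))) {
    abort("cohort must have columns patient_id, stage, recording_id, data")
  }
  stages <- as_stage(cohort$stage)
  if (!all(stage_levels() %in% as.character(stages))) {
    abort("all three stage groups must be non-empty")
  }
  per_pat <- table(cohort$patient_id)
  if (any(per_pat < 2 | per_pat > 8)) {
    abort("every patient must have between 2 and 8 recordings")
  }
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort$data[[i]]
    id <- cohort$recording_id[[i]]
    if (!all(c("t", "ax", "ay", "az") %in% names(rec))) {
      abort(paste0("recording ", id, ": missing columns"))
    }
    if (nrow(rec) < 16) {
      abort(paste0("recording ", id, ": fewer than 16 samples"))
    }
    dt <- diff(rec$t)
    if (any(dt <= 0)) {
      abort(paste0("recording ", id, ": timestamps not strictly increasing"))
    }
    if (mean(dt) < 0.5 / rate_hz || mean(dt) > 2 / rate_hz) {
      abort(paste0("recording ", id, ": mean sampling interval outside ",
                   "[0.5x, 2x] of the nominal rate"))
    }
    if (!all(is.finite(rec$ax) & is.finite(rec$ay) & is.finite(rec$az))) {
      abort(paste0("recording ", id, ": non-finite accelerations"))
    }
  }
  invisible(cohort)
}

#' Write a cohort to a directory of CSV logs
#'
#' One CSV per recording (columns `t,ax,ay,az`; seconds and m/s^2, the format
#' an Android accelerometer logger saves) plus a `manifest.csv` with columns
#' `file,patient_id,stage`.
#'
#' @param cohort An `sw_cohort` tibble.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(cohort$recording_id, ".csv")
  purrr::walk2(cohort$data, files, function(rec, f) {
    readr::write_csv(rec, file.path(dir, f))
  })
  manifest <- tibble(file = files,
                     patient_id = cohort$patient_id,
                     stage = as.character(cohort$stage))
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mpath)
  invisible(mpath)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the recording CSVs.
#' @return An `sw_cohort` tibble; recording invariants are enforced on read.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) abort(paste0("no manifest.csv in ", dir))
  manifest <- readr::read_csv(mpath, show_col_types = FALSE)
  if (!all(c("file", "patient_id", "stage") %in% names(manifest))) {
    abort("manifest.csv must have columns file, patient_id, stage")
  }
  manifest$stage <- as_stage(manifest$stage)
  data <- purrr::map(manifest$file, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) {
      abort(paste0("manifest references absent file: ", f))
    }
    rec <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_double()))
    if (!all(c("t", "ax", "ay", "az") %in% names(rec))) {
      abort(paste0(f, ": expected columns t, ax, ay, az"))
    }
    if (anyNA(rec)) {
      abort(paste0(f, ": malformed row at line ",
                   which(rowSums(is.na(rec)) > 0)[1] + 1L))
    }
    bad <- which(diff(rec$t) <= 0)
    if (length(bad) > 0) {
      abort(paste0(f, ": non-monotone timestamp at line ", bad[1] + 2L))
    }
    rec[, c("t", "ax", "ay", "az")]
  })
  out <- new_cohort(tibble(
    patient_id = manifest$patient_id,
    stage = manifest$stage,
    recording_id = sub("\\.csv$", "", manifest$file),
    data = data
  ))
  validate_cohort(out)
  out
}

#' @export
print.sw_cohort <- function(x, ...) {
  if (!all(c("patient_id", "stage", "data") %in% names(x))) {
    return(NextMethod())
  }
  cat(sprintf("<sw_cohort> %d recordings, %d patients (%s)\n",
              nrow(x), dplyr::n_distinct(x$patient_id),
              paste(sprintf("%s: %d", names(table(x$stage)), table(x$stage)),
                    collapse = ", ")))
  NextMethod()
}
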