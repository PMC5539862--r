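#' Per-second or per-minute aggregation of a recording
#'
#' Bins the raw samples of each axis into half-open intervals (t-1, t]
#' (seconds, t = 1..s_i with s_i the ceiling of the final timestamp) or
#' (t-1, t] in minutes (t = 1..m_i, m_i the ceiling of the final timestamp
#' over 60), and computes the sum, median and mean of the accelerations in
#' each bin. A sample logged at exactly t = 0 is assigned to the first bin.
#' Bins left empty by sampling jitter carry forward the previous bin's
#' values; leading empty bins are backfilled from the first non-empty bin.
#'
#' @param rec A recording tibble with columns `t`, `ax`, `ay`, `az`.
#' @param resolution `"second"` or `"minute"`.
#' @return A tibble with columns `axis`, `bin`, `sum`, `median`, `mean`.
#' @examples
#' rec <- tibble::tibble(t = seq(0, 9.9, by = 0.125),
#'                       ax = 1, ay = 2, az = 3)
#' aggregate_recording(rec, "second")
#' @export
aggregate_recording <- function(rec, resolution = c("second", "minute")) {
  resolution <- match.arg(resolution)
  if (!is.data.frame(rec) || nrow(rec) == 0) {
    abort("recording must be a non-empty data frame")
  }
  scale <- if (resolution == "second") 1 else 60
  n_bins <- as.integer(ceiling(rec$t[nrow(rec)] / scale))
  if (n_bins < 1) n_bins <- 1L
  bin <- pmax(1L, as.integer(ceiling(rec$t / scale)))
  purrr::map(c("ax", "ay", "az"), function(a) {
    v <- rec[[a]]
    agg <- tibble(bin = seq_len(n_bins)) %>%
      left_join(
        tibble(bin = bin, v = v) %>%
          group_by(.data$bin) %>%
          summarise(sum = sum(.data$v), median = median(.data$v),
                    mean = mean(.data$v), .groups = "drop"),
        by = "bin")
    # carry forward over empty bins; backfill leading empties
    for (col in c("sum", "median", "mean")) {
      x <- agg[[col]]
      filled <- !is.na(x)
      if (!any(filled)) abort("no samples fall in any bin")
      idx <- cummax(ifelse(filled, seq_along(x), 0L))
      idx[idx == 0L] <- which(filled)[1]
      agg[[col]] <- x[idx]
    }
    agg$axis <- sub("^a", "", a)
    agg
  }) %>%
    bind_rows() %>%
    select("axis", "bin", "sum", "median", "mean")
}

#' Five summary statistics of a series
#'
#' @param x Non-empty numeric vector.
#' @return Named numeric: `sum`, `mean`, `median`, `min`, `max`.
#' @export
summarize_series <- function(x) {
  if (length(x) == 0) abort("series must be non-empty")
  c(sum = sum(x), mean = mean(x), median = median(x),
    min = min(x), max = max(x))
}

#' Speed and displacement by trapezoidal integration
#'
#' Cumulatively integrates each acceleration axis over the raw timestamps
#' (trapezoidal rule, initial value 0) to obtain speed, and integrates speed
#' again to obtain displacement.
#'
#' @param rec A recording tibble with columns `t`, `ax`, `ay`, `az` and at
#'   least two samples.
#' @return A tibble with columns `t`, `vx`, `vy`, `vz`, `sx`, `sy`, `sz`
#'   (speed in m/s, displacement in m).
#' @export
integrate_kinematics <- function(rec) {
  if (!is.data.frame(rec) || nrow(rec) < 2) {
    abort("at least two samples are required to integrate")
  }
  out <- tibble(t = rec$t)
  for (a in c("x", "y", "z")) {
    v <- as.numeric(pracma::cumtrapz(rec$t, rec[[paste0("a", a)]]))
    s <- as.numeric(pracma::cumtrapz(rec$t, v))
    out[[paste0("v", a)]] <- v
    out[[paste0("s", a)]] <- s
  }
  out
}

feature_schema <- function(mode = c("basic90", "extended")) {
  mode <- match.arg(mode)
  series <- c("acc")
  if (mode == "extended") series <- c("acc", "speed", "disp")
  grid <- expand.grid(
    stat = c("sum", "mean", "median", "min", "max"),
    agg = c("sum", "median", "mean"),
    resolution = c("sec", "min"),
    series = series,
    axis = c("x", "y", "z"),
    stringsAsFactors = FALSE
  )
  # order: axis (x,y,z) > series > resolution (sec,min) > agg > stat
  grid <- grid[order(match(grid$axis, c("x", "y", "z")),
                     match(grid$series, series),
                     match(grid$resolution, c("sec", "min")),
                     match(grid$agg, c("sum", "median", "mean")),
                     match(grid$stat, c("sum", "mean", "median", "min", "max"))), ]
  paste(grid$axis, grid$series, grid$resolution, grid$agg, grid$stat,
        sep = "_")
}

extract_features_one <- function(rec, mode) {
  series_tbls <- list(acc = rec)
  if (mode == "extended") {
    kin <- integrate_kinematics(rec)
    series_tbls$speed <- tibble(t = kin$t, ax = kin$vx, ay = kin$vy,
                                az = kin$vz)
    series_tbls$disp <- tibble(t = kin$t, ax = kin$sx, ay = kin$sy,
                               az = kin$sz)
  }
  vals <- purrr::imap(series_tbls, function(tbl, nm) {
    purrr::map(c(sec = "second", min = "minute"), function(res) {
      agg <- aggregate_recording(tbl, res)
      purrr::map(c("x", "y", "z"), function(ax) {
        sub <- agg[agg$axis == ax, ]
        purrr::map(c("sum", "median", "mean"), function(a) {
          summarize_series(sub[[a]])
        })
      })
    })
  })
  schema <- feature_schema(mode)
  out <- numeric(length(schema))
  k <- 0L
  series <- names(series_tbls)
  for (ax_i in 1:3) {
    for (se in series) {
      for (res in c("sec", "min")) {
        for (agg_i in 1:3) {
          out[k + 1:5] <- vals[[se]][[res]][[ax_i]][[agg_i]]
          k <- k + 5L
        }
      }
    }
  }
  setNames(out, schema)
}

#' Fixed-width feature vectors for variable-length recordings
#'
#' Reduces every recording, whatever its duration and sampling grid, to the
#' same fixed-width numeric vector so that multivariate classifiers can be
#' applied. In `basic90` mode the layout is: for each axis (x, y, z), each
#' time resolution (second, minute) and each per-bin aggregate series (sum,
#' median, mean), the five summary statistics (sum, mean, median, min, max)
#' of that series — 3 x 2 x 3 x 5 = 90 features, the input width of the
#' neural-network classifier. `extended` mode additionally applies the same
#' scheme to the speed and displacement curves from
#' [integrate_kinematics()], giving 270 features.
#'
#' @param cohort An `sw_cohort` tibble (or any tibble of recordings with
#'   `recording_id`, `patient_id`, `stage`, `data`).
#' @param mode `"basic90"` or `"extended"`.
#' @return A tibble with one row per recording: `recording_id`,
#'   `patient_id`, `stage`, then the feature columns in schema order.
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' feats <- extract_features(cohort[1:3, ])
#' ncol(feats) - 3
#' @export
extract_features <- function(cohort, mode = c("basic90", "extended")) {
  mode <- match.arg(mode)
  rows <- purrr::map(cohort$data, extract_features_one,
                     mode = if (mode == "basic90") "basic90" else "extended")
  feats <- as_tibble(do.call(rbind, rows))
  bind_cols(tibble(recording_id = cohort$recording_id,
                   patient_id = cohort$patient_id,
                   stage = as_stage(cohort$stage)),
            feats)
}

feature_columns <- function(features) {
  setdiff(names(features), c("recording_id", "patient_id", "stage"))
}
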