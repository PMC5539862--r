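#' Tidy a functional test result
#'
#' @param x An `sw_test`.
#' @param ... Unused.
#' @return One-row tibble with `method`, `statistic`, `p_value`.
#' @export
tidy.sw_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value)
}

#' @rdname tidy.sw_test
#' @export
glance.sw_test <- function(x, ...) tidy(x)

#' Tidy a repeated-windowing p-value summary
#'
#' One row in the layout of the repeated-test summary table: mean and
#' standard deviation of the J p-values and the proportion at or below 0.05.
#'
#' @param x An `sw_pvalue_summary`.
#' @param ... Unused.
#' @export
tidy.sw_pvalue_summary <- function(x, ...) {
  tibble(test = x$test, axis = x$axis,
         comparison = if (is.null(x$stages)) NA_character_ else
           paste(x$stages, collapse = " vs "),
         mean = x$mean, sd = x$sd, prop_le_05 = x$prop_le_05,
         n_reps = x$n_reps)
}

#' @rdname tidy.sw_pvalue_summary
#' @export
glance.sw_pvalue_summary <- function(x, ...) tidy(x)

#' Tidy a classification report
#'
#' @param x An `sw_report`.
#' @param ... Unused.
#' @return Per-stage rows (plus a `total` row) with `n`, `misclassified`,
#'   `success_rate`.
#' @export
tidy.sw_report <- function(x, ...) {
  bind_cols(tibble(method = x$method), x$by_stage)
}

#' @rdname tidy.sw_report
#' @export
glance.sw_report <- function(x, ...) {
  tot <- x$by_stage[x$by_stage$stage == "total", ]
  tibble(method = x$method, n = tot$n, misclassified = tot$misclassified,
         success_rate = tot$success_rate)
}

#' Model-level summary of a fitted network
#'
#' @param x An `sw_mlp`.
#' @param ... Unused.
#' @export
glance.sw_mlp <- function(x, ...) {
  tibble(inputs = x$sizes[1],
         hidden = paste(x$sizes[-c(1, length(x$sizes))], collapse = "-"),
         encoding = x$encoding, converged = x$converged,
         iterations = x$iterations, loss = x$loss)
}

#' Tidy a patient-grouped split
#'
#' @param x An `sw_split`.
#' @param ... Unused.
#' @export
tidy.sw_split <- function(x, ...) x$counts

#' Per-depth summary of a layer sweep
#'
#' @param x An `sw_sweep`.
#' @param ... Unused.
#' @export
tidy.sw_sweep <- function(x, ...) {
  x %>%
    as_tibble() %>%
    group_by(layers = .data$layers) %>%
    summarise(median = median(.data$misclassification),
              mean = mean(.data$misclassification),
              min = min(.data$misclassification),
              max = max(.data$misclassification),
              n_networks = dplyr::n(), .groups = "drop")
}
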