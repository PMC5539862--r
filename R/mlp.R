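# Feed-forward network with logistic activations trained by resilient
# backpropagation with weight backtracking (rprop+), full-batch gradients.
# Two output encodings: a single logistic unit with stage targets
# 0 / 0.5 / 1 and decision thresholds 0.25 / 0.75 (default), or three
# softmax units with one-hot targets.

logistic <- function(x) 1 / (1 + exp(-x))

mlp_forward <- function(weights, x, encoding) {
  acts <- list(cbind(1, x))
  L <- length(weights)
  for (k in seq_len(L)) {
    z <- acts[[k]] %*% weights[[k]]
    a <- if (k < L) {
      logistic(z)
    } else if (encoding == "scalar") {
      logistic(z)
    } else {
      e <- exp(z - apply(z, 1, max))
      e / rowSums(e)
    }
    acts[[k + 1]] <- if (k < L) cbind(1, a) else a
  }
  acts
}

mlp_gradients <- function(weights, x, y, encoding) {
  acts <- mlp_forward(weights, x, encoding)
  L <- length(weights)
  out <- acts[[L + 1]]
  n <- nrow(x)
  # scalar: E = sum((o - y)^2) / 2, logistic output -> delta = (o-y) o (1-o)
  # softmax + cross-entropy -> delta = o - y
  delta <- if (encoding == "scalar") (out - y) * out * (1 - out) else out - y
  loss <- if (encoding == "scalar") {
    sum((out - y)^2) / 2
  } else {
    -sum(y * log(pmax(out, 1e-12)))
  }
  grads <- vector("list", L)
  for (k in rev(seq_len(L))) {
    grads[[k]] <- t(acts[[k]]) %*% delta
    if (k > 1) {
      a <- acts[[k]][, -1, drop = FALSE] # strip bias column
      delta <- (delta %*% t(weights[[k]][-1, , drop = FALSE])) * a * (1 - a)
    }
  }
  list(grads = grads, loss = loss)
}

rprop_train <- function(weights, x, y, encoding, max_iter, threshold) {
  eta_plus <- 1.2; eta_minus <- 0.5
  d_max <- 50; d_min <- 1e-6
  delta <- lapply(weights, function(w) array(0.1, dim(w)))
  g_old <- lapply(weights, function(w) array(0, dim(w)))
  dw_old <- lapply(weights, function(w) array(0, dim(w)))
  converged <- FALSE
  it <- 0L
  loss <- NA_real_
  while (it < max_iter) {
    it <- it + 1L
    gr <- mlp_gradients(weights, x, y, encoding)
    loss <- gr$loss
    gmax <- max(vapply(gr$grads, function(g) max(abs(g)), numeric(1)))
    if (gmax < threshold) {
      converged <- TRUE
      break
    }
    for (k in seq_along(weights)) {
      g <- gr$grads[[k]]
      s <- g * g_old[[k]]
      same <- s > 0
      flip <- s < 0
      delta[[k]][same] <- pmin(delta[[k]][same] * eta_plus, d_max)
      delta[[k]][flip] <- pmax(delta[[k]][flip] * eta_minus, d_min)
      dw <- -sign(g) * delta[[k]]
      dw[flip] <- -dw_old[[k]][flip] # backtrack the previous update
      weights[[k]] <- weights[[k]] + dw
      g[flip] <- 0
      g_old[[k]] <- g
      dw_old[[k]] <- dw
    }
  }
  list(weights = weights, converged = converged, iterations = it,
       loss = loss)
}

#' Train the neural-network stage classifier
#'
#' Fits a feed-forward network with logistic hidden activations on the
#' standardised feature vectors of the training recordings, trained by
#' resilient backpropagation with weight backtracking (rprop+), full batch,
#' for at most `max_iter` iterations (convergence when the largest absolute
#' partial derivative drops below `threshold`). The default architecture has
#' one hidden layer of 175 neurons and a single logistic output unit with
#' numeric stage targets early = 0, middle = 0.5, late = 1 (decision
#' thresholds 0.25 and 0.75); `encoding = "softmax"` uses three softmax
#' output units instead. Features are z-scored with training-set statistics
#' stored in the model (constant features get unit scale).
#'
#' @param features Training tibble from [extract_features()] (or any tibble
#'   with a `stage` column and numeric feature columns; `recording_id` and
#'   `patient_id` are ignored for fitting).
#' @param hidden Integer vector of hidden-layer sizes.
#' @param seed Integer seed for the initial weights (uniform on
#'   \[-0.5, 0.5\]).
#' @param encoding `"scalar"` (one logistic output) or `"softmax"`.
#' @param max_iter Maximum rprop+ iterations.
#' @param threshold Convergence threshold on the gradient.
#' @return An `sw_mlp` model; see [predict.sw_mlp()] and [glance.sw_mlp()].
#' @export
train_nn <- function(features, hidden = 175, seed = NULL,
                     encoding = c("scalar", "softmax"),
                     max_iter = 1000, threshold = 0.01) {
  encoding <- match.arg(encoding)
  if (any(hidden < 1)) abort("hidden layer sizes must be positive")
  stage <- as_stage(features$stage)
  cols <- feature_columns(features)
  x <- as.matrix(features[, cols])
  if (!all(is.finite(x))) abort("non-finite feature values")
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  y <- if (encoding == "scalar") {
    matrix(c(early = 0, middle = 0.5, late = 1)[as.character(stage)], ncol = 1)
  } else {
    yy <- matrix(0, nrow(x), 3, dimnames = list(NULL, stage_levels()))
    yy[cbind(seq_len(nrow(x)), as.integer(stage))] <- 1
    yy
  }
  sizes <- c(ncol(x), hidden, ncol(y))
  weights <- with_seed_if(seed, {
    lapply(seq_len(length(sizes) - 1), function(k) {
      matrix(runif((sizes[k] + 1) * sizes[k + 1], -0.5, 0.5),
             nrow = sizes[k] + 1)
    })
  })
  fit <- rprop_train(weights, xs, y, encoding, max_iter, threshold)
  structure(list(weights = fit$weights, sizes = sizes, encoding = encoding,
                 center = center, scale = scl, feature_names = cols,
                 prevalence = table(stage) / length(stage),
                 converged = fit$converged, iterations = fit$iterations,
                 loss = fit$loss, seed = seed),
            class = "sw_mlp")
}

#' @export
print.sw_mlp <- function(x, ...) {
  cat(sprintf(
    "<sw_mlp> %s -> %s -> %d (%s), %d iterations, %sconverged\n",
    x$sizes[1], paste(x$sizes[-c(1, length(x$sizes))], collapse = "-"),
    x$sizes[length(x$sizes)], x$encoding, x$iterations,
    if (x$converged) "" else "not "))
  invisible(x)
}

#' Predict stages for new recordings
#'
#' @param object An `sw_mlp` model.
#' @param newdata Feature tibble with the model's feature columns.
#' @param type `"stage"` for predicted stage labels, `"raw"` for the network
#'   outputs.
#' @param ... Unused.
#' @return Factor of stages, or the raw output matrix.
#' @export
predict.sw_mlp <- function(object, newdata, type = c("stage", "raw"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[, object$feature_names])
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  out <- mlp_forward(object$weights, xs, object$encoding)[[length(object$weights) + 1]]
  if (type == "raw") return(out)
  if (object$encoding == "scalar") {
    cut_pts <- cut(out[, 1], breaks = c(-Inf, 0.25, 0.75, Inf),
                   labels = stage_levels())
    factor(as.character(cut_pts), levels = stage_levels())
  } else {
    factor(stage_levels()[max.col(out, ties.method = "first")],
           levels = stage_levels())
  }
}
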