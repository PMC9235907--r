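#' Goodness-of-fit measures and calibration loss
#'
#' DEBtool-style relative goodness-of-fit measures. Both operate on aligned
#' prediction/observation sets: either single numeric vectors (one dataset)
#' or lists of datasets, each a list with elements `pred`, `obs` and
#' optionally `weights`. Every dataset contributes equally to the final
#' average (zero-variate scalars each count as their own dataset).
#'
#' `mean_relative_error()` is the across-dataset mean of the per-dataset
#' weighted mean of `|pred - obs| / |obs|`.
#'
#' `symmetric_mean_squared_error()` is the across-dataset mean of the
#' per-dataset weighted mean squared error normalized by
#' `mean(obs^2) + mean(pred^2)`; bounded in \[0, 1\] for non-negative data
#' and invariant under unit rescaling of any single dataset.
#'
#' @param predictions,observations numeric vectors, or lists of datasets
#' @param weights per-point weights (single-dataset form only); default 1
#' @return scalar measure; per-dataset values attached as attribute
#'   `"per_dataset"`
#' @examples
#' mean_relative_error(1.1, 1.0)                      # 0.1
#' symmetric_mean_squared_error(1, 2)                 # 1/5
#' @name goodness_of_fit
NULL

as_datasets <- function(predictions, observations, weights) {
  if (is.list(predictions)) {
    stopifnot(is.list(observations), length(predictions) == length(observations))
    mapply(function(p, o) {
      if (is.list(p)) p else list(pred = p, obs = o, weights = NULL)
    }, predictions, observations, SIMPLIFY = FALSE)
  } else {
    list(list(pred = predictions, obs = observations, weights = weights))
  }
}

dataset_weights <- function(d) {
  w <- d$weights
  if (is.null(w)) w <- rep(1, length(d$obs))
  if (length(w) != length(d$obs)) stop("weights length mismatch")
  if (any(w < 0)) stop("weights must be non-negative")
  w
}

#' @rdname goodness_of_fit
#' @export
mean_relative_error <- function(predictions, observations, weights = NULL) {
  ds <- as_datasets(predictions, observations, weights)
  per <- vapply(seq_along(ds), function(i) {
    d <- ds[[i]]
    if (length(d$pred) != length(d$obs)) stop("aligned sets required")
    w <- dataset_weights(d)
    zero <- d$obs == 0 & w > 0
    if (any(zero))
      stop("relative error undefined for zero observation (dataset ", i,
           ", point ", which(zero)[1], ")")
    sum(w * abs(d$pred - d$obs) / abs(d$obs)) / sum(w)
  }, numeric(1))
  structure(mean(per), per_dataset = per)
}

#' @rdname goodness_of_fit
#' @export
symmetric_mean_squared_error <- function(predictions, observations,
                                         weights = NULL) {
  ds <- as_datasets(predictions, observations, weights)
  per <- vapply(seq_along(ds), function(i) {
    d <- ds[[i]]
    if (length(d$pred) != length(d$obs)) stop("aligned sets required")
    w <- dataset_weights(d)
    norm <- mean(d$obs^2) + mean(d$pred^2)
    if (norm == 0)
      stop("symmetric error undefined for all-zero dataset ", i)
    (sum(w * (d$pred - d$obs)^2) / sum(w)) / norm
  }, numeric(1))
  structure(mean(per), per_dataset = per)
}

#' Calibration loss
#'
#' The weighted symmetric quadratic loss minimized by [fit_deb()]:
#' `sum over datasets of sum_i w_i (p_i - d_i)^2 / (mean(d^2) + mean(p^2))`
#' — the same kernel as [symmetric_mean_squared_error()] without the final
#' normalization to \[0, 1\]. This objective is the package's frozen,
#' reproducible definition of fit quality.
#'
#' @inheritParams goodness_of_fit
#' @return scalar loss, >= 0
#' @export
deb_loss <- function(predictions, observations, weights = NULL) {
  ds <- as_datasets(predictions, observations, weights)
  sum(vapply(seq_along(ds), function(i) {
    d <- ds[[i]]
    if (length(d$pred) != length(d$obs)) stop("aligned sets required")
    w <- dataset_weights(d)
    norm <- mean(d$obs^2) + mean(d$pred^2)
    if (norm == 0)
      stop("loss undefined for all-zero dataset ", i)
    sum(w * (d$pred - d$obs)^2) / norm
  }, numeric(1)))
}
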