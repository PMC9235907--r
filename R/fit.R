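#' Optimizer settings for [fit_deb()]
#'
#' @param maxit maximum Nelder-Mead evaluations per start
#' @param reltol relative convergence tolerance on the loss
#' @param restart perform one seeded random restart from a jittered optimum
#'   and keep the better result
#' @param restart_sd standard deviation of the restart jitter on the
#'   transformed (log/logit) scale
#' @param seed seed scoping the restart jitter
#' @param collinearity_tol singular-value ratio below which the free set is
#'   flagged as under-determined by the data
#' @return list of class `fit_control`
#' @export
fit_control <- function(maxit = 10000, reltol = 1e-10, restart = TRUE,
                        restart_sd = 0.05, seed = 1,
                        collinearity_tol = 1e-7) {
  structure(list(maxit = maxit, reltol = reltol, restart = restart,
                 restart_sd = restart_sd, seed = seed,
                 collinearity_tol = collinearity_tol),
            class = "fit_control")
}

#' Fit DEB parameters to an observation set
#'
#' Minimizes the weighted symmetric loss ([deb_loss()]) over a chosen set of
#' free parameters by the Nelder-Mead simplex (standard
#' reflection/expansion/contraction coefficients 1, 2, 0.5, 0.5). Positive
#' parameters are optimized on the log scale and allocation fractions
#' (`kappa`, `kappa_R`, `kappa_X`) on the logit scale, so parameter
#' invariants hold by construction. One seeded random restart from the
#' jittered optimum guards against premature simplex collapse; the result is
#' deterministic given the inputs and the seed in `config`.
#'
#' Before optimizing, the sensitivity of the stacked predictions to the free
#' parameters is checked at the start values; a rank-deficient Jacobian
#' (e.g. `k_b` and `b_max` fitted jointly from moisture-response data, where
#' only their ratio enters) raises a collinearity warning.
#'
#' @param obs an [observation_set()]
#' @param params0 starting/fixed parameter values, a [deb_params()]
#' @param free character vector of parameter names to estimate; empty means
#'   evaluation only
#' @param config a [fit_control()]
#' @param control a [deb_control()] passed to the simulations
#' @return object of class `deb_fit`: list with `params` (fitted),
#'   `free`, `loss`, `MRE`, `SMSE`, `per_dataset_re` (named per-dataset
#'   relative errors), `convergence` (0 = converged), `evaluations`,
#'   `collinear` (logical), `start_loss`
#' @examples
#' obs <- observation_set(datasets = list(
#'   deb_dataset("diapause", "diapause_fraction", x = c(9, 10, 12),
#'               obs = diapause_fraction(c(9, 10, 12), deb_params()))))
#' fit_deb(obs, deb_params(), free = character())$MRE   # 0: exact data
#' @export
fit_deb <- function(obs, params0 = deb_params(), free = character(),
                    config = fit_control(), control = deb_control()) {
  stopifnot(inherits(obs, "observation_set"))
  bad <- setdiff(free, names(params0))
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "))

  objective <- function(x) {
    p <- tryCatch(untransform_params(x, free, params0),
                  error = function(e) NULL)
    if (is.null(p)) return(1e10)
    preds <- tryCatch(predict_observations(obs, p, control),
                      error = function(e) NULL)
    if (is.null(preds)) return(1e10)
    sets <- aligned_sets(obs, preds)
    val <- tryCatch(deb_loss(sets, sets), error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }

  eval_at <- function(p) {
    preds <- predict_observations(obs, p, control)
    sets <- aligned_sets(obs, preds)
    # zero observations carry no relative-error information: weight them
    # out of the MRE report (the loss itself handles them fine)
    mre_sets <- lapply(sets, function(s) {
      w <- if (is.null(s$weights)) rep(1, length(s$obs)) else s$weights
      w[s$obs == 0] <- 0
      s$weights <- w
      s
    })
    mre_sets <- Filter(function(s) sum(s$weights) > 0, mre_sets)
    mre <- mean_relative_error(mre_sets, mre_sets)
    smse <- symmetric_mean_squared_error(sets, sets)
    per <- attr(mre, "per_dataset")
    names(per) <- vapply(mre_sets, `[[`, "", "name")
    list(loss = deb_loss(sets, sets), MRE = as.numeric(mre),
         SMSE = as.numeric(smse), per_dataset_re = per)
  }

  start_preds <- tryCatch(predict_observations(obs, params0, control),
                          error = function(e)
                            stop("predictions failed at starting values: ",
                                 conditionMessage(e)))
  start_sets <- aligned_sets(obs, start_preds)
  for (s in start_sets)
    if (any(!is.finite(s$pred)))
      stop("non-finite prediction at starting values in dataset '",
           s$name, "'")
  start_loss <- deb_loss(start_sets, start_sets)

  collinear <- FALSE
  if (length(free) >= 2) {
    collinear <- check_collinearity(obs, params0, free, control,
                                    config$collinearity_tol)
    if (collinear)
      warning("free parameter set {", paste(free, collapse = ", "),
              "} is under-determined by the data ",
              "(rank-deficient prediction sensitivity)")
  }

  if (length(free) == 0) {
    ev <- eval_at(params0)
    return(structure(c(list(params = params0, free = free,
                            convergence = 0, evaluations = 0,
                            collinear = collinear, start_loss = start_loss),
                       ev),
                     class = "deb_fit"))
  }

  # optim advises against 1-D Nelder-Mead; the simplex is still the
  # normative algorithm here, so muffle that specific advisory
  nm <- function(x)
    withCallingHandlers(
      stats::optim(x, objective, method = "Nelder-Mead",
                   control = list(maxit = config$maxit,
                                  reltol = config$reltol)),
      warning = function(w) {
        if (grepl("one-di", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  x0 <- transform_params(params0, free)
  opt <- nm(x0)
  evals <- opt$counts[["function"]]
  if (config$restart) {
    x1 <- withr::with_seed(config$seed,
      opt$par + stats::rnorm(length(free), sd = config$restart_sd))
    opt2 <- nm(x1)
    evals <- evals + opt2$counts[["function"]]
    if (opt2$value < opt$value) opt <- opt2
  }
  if (opt$convergence == 1)
    warning("Nelder-Mead evaluation cap reached before convergence")

  params_hat <- untransform_params(opt$par, free, params0)
  ev <- eval_at(params_hat)
  structure(c(list(params = params_hat, free = free,
                   convergence = opt$convergence,
                   evaluations = unname(evals), collinear = collinear,
                   start_loss = start_loss),
              ev),
            class = "deb_fit")
}

# finite-difference Jacobian of stacked predictions w.r.t. transformed free
# parameters; rank deficiency signals non-identifiability
check_collinearity <- function(obs, params0, free, control, tol) {
  x0 <- transform_params(params0, free)
  stack <- function(x) {
    p <- untransform_params(x, free, params0)
    preds <- predict_observations(obs, p, control)
    unlist(lapply(aligned_sets(obs, preds), `[[`, "pred"))
  }
  f0 <- stack(x0)
  h <- 1e-5
  J <- vapply(seq_along(x0), function(j) {
    xp <- x0; xp[j] <- xp[j] + h
    (stack(xp) - f0) / h
  }, numeric(length(f0)))
  sv <- svd(J)$d
  if (max(sv) == 0) return(TRUE)
  min(sv) / max(sv) < tol
}

#' @export
print.deb_fit <- function(x, ...) {
  cat("<deb_fit> ", if (length(x$free)) paste(length(x$free), "free parameter(s):",
      paste(x$free, collapse = ", ")) else "evaluation only", "\n", sep = "")
  cat("  loss = ", format(x$loss), ", MRE = ", format(round(x$MRE, 4)),
      ", SMSE = ", format(round(x$SMSE, 4)), "\n", sep = "")
  if (length(x$free)) {
    est <- unlist(x$params[x$free])
    print(est, ...)
  }
  invisible(x)
}
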