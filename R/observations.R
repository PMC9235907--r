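#' Calibration dataset (uni-variate)
#'
#' One response curve: an independent-variable series, observed values,
#' per-point weights, and the mapping to a model observable plus the
#' scenario constants needed to predict it.
#'
#' @param name dataset identifier
#' @param observable one of the registered observables, see
#'   [predict_observations()]
#' @param x independent variable values (units depend on the observable)
#' @param obs observed values, same length as `x`
#' @param weights per-point weights; default `1/n` so each dataset
#'   contributes equally to the loss
#' @param scenario named list of scenario constants consumed by the
#'   observable extractor (e.g. `L`, `T_C`, `OM`, `M`, `duration`, `L_0`,
#'   `e_0`, `f`, `f_adult`, `gut_content`, `initial`)
#' @return list of class `deb_dataset`
#' @export
deb_dataset <- function(name, observable, x, obs,
                        weights = rep(1 / length(obs), length(obs)),
                        scenario = list()) {
  if (length(x) != length(obs)) stop("x and obs must have equal length")
  if (length(weights) != length(obs)) stop("weights length mismatch")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (!observable %in% names(observable_registry()))
    stop("unknown observable '", observable, "'; registered: ",
         paste(names(observable_registry()), collapse = ", "))
  structure(list(name = name, observable = observable, x = x, obs = obs,
                 weights = weights, scenario = scenario),
            class = "deb_dataset")
}

#' Observation set for calibration
#'
#' Bundles zero-variate scalars and uni-variate datasets.
#'
#' @param zero_variate data.frame with columns `name`, `value` and
#'   optionally `weight` (default 1); names must match the outputs of
#'   [predict_zero_variate()]
#' @param datasets list of [deb_dataset()] objects
#' @return list of class `observation_set`
#' @export
observation_set <- function(zero_variate = NULL, datasets = list()) {
  if (!is.null(zero_variate)) {
    stopifnot(is.data.frame(zero_variate),
              all(c("name", "value") %in% names(zero_variate)))
    if (is.null(zero_variate$weight)) zero_variate$weight <- 1
    known <- c("time_since_birth_at_puberty", "length_at_birth",
               "ultimate_length", "fresh_weight_at_birth",
               "fresh_weight_at_puberty", "ultimate_fresh_weight")
    bad <- setdiff(zero_variate$name, known)
    if (length(bad)) stop("unknown zero-variate name(s): ",
                          paste(bad, collapse = ", "))
  }
  for (d in datasets)
    if (!inherits(d, "deb_dataset")) stop("datasets must be deb_dataset objects")
  nm <- vapply(datasets, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate dataset names")
  structure(list(zero_variate = zero_variate, datasets = datasets),
            class = "observation_set")
}

# Each extractor maps (x, scenario constants, params) -> predictions.
# `cache` carries per-parameter-vector intermediates (embryo time).
observable_registry <- function() {
  sim_curve <- function(column) {
    function(x, sc, params, control, cache) {
      env <- deb_environment(T_C = sc$T_C %||% 20, M = sc$M %||% 20,
                             OM = sc$OM %||% 4)
      scn <- deb_scenario(env, duration = max(x),
                         initial = sc$initial %||% "juvenile",
                         L_0 = sc$L_0, e_0 = sc$e_0 %||% 1,
                         f = sc$f, f_adult = sc$f_adult,
                         gut_content = sc$gut_content %||% 0,
                         times = sort(unique(c(x, max(x)))))
      tr <- simulate_deb(scn, params, control)
      stats::approx(tr$states$time, tr$states[[column]], xout = x,
                    rule = 2)$y
    }
  }
  per_level_final <- function(column, rate_per_week = FALSE) {
    function(x, sc, params, control, cache) {
      vapply(x, function(M) {
        env <- deb_environment(T_C = sc$T_C %||% 20, M = M,
                               OM = sc$OM %||% 4)
        scn <- deb_scenario(env, duration = sc$duration,
                           initial = sc$initial %||% "juvenile",
                           L_0 = sc$L_0, e_0 = sc$e_0 %||% 1,
                           gut_content = sc$gut_content %||% 0,
                           times = c(0, sc$duration))
        tr <- simulate_deb(scn, params, control)
        val <- utils::tail(tr$states[[column]], 1)
        if (rate_per_week) val / sc$duration * 7 else val
      }, numeric(1))
    }
  }
  list(
    cast_rate = function(x, sc, params, control, cache)
      cast_production_rate(sc$OM, sc$L, x, params),
    burrow_rate = function(x, sc, params, control, cache)
      burrow_rate(x, sc$L, params,
                  temperature_correction(sc$T_C %||% 20, params)),
    relative_burrow_om = function(x, sc, params, control, cache)
      om_functional_response(x, sc$L %||% 1, params)$f_OM,
    moisture_response = function(x, sc, params, control, cache)
      moisture_functional_response(x, params),
    diapause_fraction = function(x, sc, params, control, cache)
      diapause_fraction(x, params),
    dev_time = function(x, sc, params, control, cache) {
      t_emb <- cache$embryo_time_ref(params)
      F_t <- temperature_correction(x, params)
      if (control$t0_temperature_corrected) (params$t_0 + t_emb) / F_t
      else params$t_0 + t_emb / F_t
    },
    fresh_weight = sim_curve("Ww_g"),
    dry_weight = sim_curve("Wd_g"),
    eggs_cum = sim_curve("eggs_cum"),
    fresh_weight_vs_moisture = per_level_final("Ww_g"),
    dry_weight_vs_moisture = per_level_final("Wd_g"),
    reproduction_rate_vs_moisture = per_level_final("eggs_cum",
                                                    rate_per_week = TRUE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# embryo integration time at reference temperature, excluding the cocoon
# delay; computed on demand once per parameter vector
make_prediction_cache <- function(control) {
  stored <- NULL; stored_key <- NULL
  list(embryo_time_ref = function(params) {
    key <- paste(unlist(params), collapse = ",")
    if (!identical(key, stored_key)) {
      env <- deb_environment(T_C = params$T_ref - 273.15, M = 20, OM = 4)
      tr <- simulate_deb(deb_scenario(env, duration = control$max_embryo_days,
                                      initial = "egg"),
                         params, control)
      if (is.na(tr$events$age_at_birth))
        stop("embryo failed to reach birth within ",
             control$max_embryo_days, " d")
      stored <<- tr$events$age_at_birth - params$t_0
      stored_key <<- key
    }
    stored
  })
}

#' Predict an observation set
#'
#' Runs the model for every dataset in an [observation_set()] and returns
#' predictions aligned with the observations. Registered observables:
#' `cast_rate` (x = temperature, deg C), `burrow_rate` (x = moisture, \%),
#' `relative_burrow_om` (x = organic matter, \%), `moisture_response`,
#' `diapause_fraction` (x = moisture), `dev_time` (x = temperature; age at
#' birth including the cocoon delay), `fresh_weight` / `dry_weight` /
#' `eggs_cum` (x = time, d; one simulation per dataset), and
#' `fresh_weight_vs_moisture` / `dry_weight_vs_moisture` /
#' `reproduction_rate_vs_moisture` (x = moisture; one simulation per level,
#' response at the end of `scenario$duration`).
#'
#' @param obs an [observation_set()]
#' @param params a [deb_params()]
#' @param control a [deb_control()]
#' @return list with `zero_variate` (named vector, possibly NULL) and
#'   `datasets` (list of lists with `pred`, `obs`, `weights`)
#' @export
predict_observations <- function(obs, params, control = deb_control()) {
  cache <- make_prediction_cache(control)
  reg <- observable_registry()
  zv <- NULL
  if (!is.null(obs$zero_variate)) {
    zv_all <- predict_zero_variate(params, control = control)
    zv <- zv_all[obs$zero_variate$name]
  }
  ds <- lapply(obs$datasets, function(d) {
    pred <- reg[[d$observable]](d$x, d$scenario, params, control, cache)
    list(name = d$name, pred = pred, obs = d$obs, weights = d$weights)
  })
  list(zero_variate = zv, datasets = ds)
}

# flatten an observation set + predictions into the dataset-list form the
# gof/loss functions consume (zero-variate entries as one-point datasets)
aligned_sets <- function(obs, preds) {
  sets <- preds$datasets
  if (!is.null(obs$zero_variate)) {
    for (i in seq_len(nrow(obs$zero_variate))) {
      sets <- c(sets, list(list(
        name = obs$zero_variate$name[i],
        pred = unname(preds$zero_variate[i]),
        obs = obs$zero_variate$value[i],
        weights = obs$zero_variate$weight[i])))
    }
  }
  sets
}
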