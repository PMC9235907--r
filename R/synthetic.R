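#' Synthetic experiment designs
#'
#' Describes one of the eight laboratory/literature experiment types the
#' model is calibrated against, with replicate counts, environmental levels,
#' observation-noise model and seed. Defaults emulate the study conditions:
#' cast production of 0.42 g worms at seven temperatures spanning 2-32 deg C
#' (n = 8), burrow rates in 2D terraria across organic matter (n = 5) and
#' moisture (n = 8, water contents 10/15/20/25 \%), diapause fractions
#' across a moisture gradient spanning the movement threshold, cocoon
#' development times at 5-20 deg C, individually-fed growth and post-pairing
#' reproduction at imposed feeding levels, and juvenile weights after 28 d
#' at different moisture contents.
#'
#' Noise model: multiplicative mean-unbiased lognormal with the stated CV
#' for positive observables (weights, casts, burrow rates, development
#' times; CV defaults 0.15 for casts, 0.10 otherwise), binomial sampling of
#' `n_per_level` worms for diapause fractions.
#'
#' @param kind experiment type, one of `"growth_food"`,
#'   `"reproduction_food"`, `"devtime_temperature"`, `"cast_temperature"`,
#'   `"burrow_om"`, `"burrow_moisture"`, `"diapause_moisture"`,
#'   `"weight_moisture"`
#' @param levels environmental or feeding levels; `NULL` for the
#'   kind-specific default
#' @param n_per_level replicates per level
#' @param duration experiment duration (d), where applicable
#' @param sampling_times observation times (d), for time-course kinds
#' @param cv observation coefficient of variation
#' @param seed integer seed; fixed seed implies bit-reproducible output
#' @return list of class `experiment_design`
#' @export
experiment_design <- function(kind, levels = NULL, n_per_level = NULL,
                              duration = NULL, sampling_times = NULL,
                              cv = NULL, seed = 1) {
  kinds <- c("growth_food", "reproduction_food", "devtime_temperature",
             "cast_temperature", "burrow_om", "burrow_moisture",
             "diapause_moisture", "weight_moisture")
  if (!kind %in% kinds)
    stop("unknown experiment kind '", kind, "'; one of: ",
         paste(kinds, collapse = ", "))
  def <- switch(kind,
    growth_food = list(levels = c(0.85, 1.0, 1.1), n = 8, cv = 0.10,
                       duration = 224,
                       sampling_times = seq(14, 224, by = 14)),
    reproduction_food = list(levels = list(c(f = 0.85, f_adult = 0.73),
                                           c(f = 1.1, f_adult = 0.87)),
                             n = 8, cv = 0.10, duration = 224,
                             sampling_times = seq(28, 224, by = 28)),
    devtime_temperature = list(levels = c(5, 10, 15, 20), n = 8, cv = 0.10,
                               duration = NULL, sampling_times = NULL),
    cast_temperature = list(levels = seq(2, 32, by = 5), n = 8, cv = 0.15,
                            duration = 14, sampling_times = NULL),
    burrow_om = list(levels = c(2, 4, 8), n = 5, cv = 0.10,
                     duration = 14, sampling_times = NULL),
    burrow_moisture = list(levels = c(10, 15, 20, 25), n = 8, cv = 0.10,
                           duration = 14, sampling_times = NULL),
    diapause_moisture = list(levels = c(5, 7.5, 10, 12.5, 15, 17.5, 20),
                             n = 8, cv = NA_real_, duration = 14,
                             sampling_times = NULL),
    weight_moisture = list(levels = c(6, 9, 12, 15, 18, 21), n = 8,
                           cv = 0.10, duration = 28, sampling_times = NULL))
  n_per_level <- n_per_level %||% def$n
  if (n_per_level < 1) stop("n_per_level must be >= 1")
  cv <- cv %||% def$cv
  if (!is.na(cv) && cv < 0) stop("cv must be >= 0")
  structure(list(kind = kind, levels = levels %||% def$levels,
                 n_per_level = n_per_level,
                 duration = duration %||% def$duration,
                 sampling_times = sampling_times %||% def$sampling_times,
                 cv = cv, seed = seed),
            class = "experiment_design")
}

# mean-unbiased multiplicative lognormal noise; zero latents stay zero
lognormal_noise <- function(latent, cv) {
  if (cv == 0) return(latent)
  sdlog <- sqrt(log1p(cv^2))
  out <- latent
  pos <- latent > 0
  out[pos] <- stats::rlnorm(sum(pos), log(latent[pos]) - sdlog^2 / 2, sdlog)
  out
}

# reference worm sizes used in the behavioural assays
assay_L <- function(params, fresh_weight_g = 0.42)
  (fresh_weight_g / (1 + params$w))^(1 / 3)

#' Generate a synthetic experiment
#'
#' Forward-simulates the model under an [experiment_design()] and applies
#' the design's observation-noise model. Returns the generated calibration
#' input together with the latent (noise-free) values and the generating
#' parameters, so recovery can be audited.
#'
#' @param design an [experiment_design()]
#' @param params generating [deb_params()]
#' @param control a [deb_control()]
#' @return list of class `synthetic_dataset` with elements
#'   `observation_set` (an [observation_set()]), `latent` (list of
#'   noise-free prediction vectors per dataset), `design`, `params`
#' @examples
#' d <- experiment_design("burrow_moisture", seed = 42)
#' syn <- generate_experiment(d, deb_params())
#' syn$observation_set$datasets[[1]]$obs
#' @export
generate_experiment <- function(design, params = deb_params(),
                                control = deb_control()) {
  stopifnot(inherits(design, "experiment_design"))
  withr::with_seed(design$seed, {
    gen <- switch(design$kind,
      cast_temperature = gen_level_noise(design, params,
        observable = "cast_rate",
        scenario = list(L = assay_L(params), OM = 4),
        latent_fun = function(x, sc)
          cast_production_rate(sc$OM, sc$L, x, params)),
      burrow_moisture = gen_level_noise(design, params,
        observable = "burrow_rate",
        scenario = list(L = assay_L(params), T_C = 20),
        latent_fun = function(x, sc)
          burrow_rate(x, sc$L, params,
                      temperature_correction(sc$T_C, params))),
      burrow_om = gen_level_noise(design, params,
        observable = "relative_burrow_om",
        scenario = list(L = assay_L(params)),
        latent_fun = function(x, sc)
          om_functional_response(x, sc$L, params)$f_OM),
      devtime_temperature = gen_level_noise(design, params,
        observable = "dev_time",
        scenario = list(),
        latent_fun = function(x, sc) {
          cache <- make_prediction_cache(control)
          observable_registry()$dev_time(x, sc, params, control, cache)
        }),
      diapause_moisture = gen_diapause(design, params),
      weight_moisture = gen_weight_moisture(design, params, control),
      growth_food = gen_growth_food(design, params, control,
                                    observable = "fresh_weight"),
      reproduction_food = gen_reproduction_food(design, params, control))
    structure(c(gen, list(design = design, params = params)),
              class = "synthetic_dataset")
  })
}

gen_level_noise <- function(design, params, observable, scenario,
                            latent_fun) {
  lv <- design$levels
  latent <- latent_fun(lv, scenario)
  x <- rep(lv, each = design$n_per_level)
  obs <- lognormal_noise(rep(latent, each = design$n_per_level), design$cv)
  ds <- deb_dataset(design$kind, observable, x, obs, scenario = scenario)
  list(observation_set = observation_set(datasets = list(ds)),
       latent = stats::setNames(list(latent), design$kind))
}

gen_diapause <- function(design, params) {
  lv <- design$levels
  latent <- diapause_fraction(lv, params)
  obs <- if (!is.na(design$cv) && design$cv == 0) latent else
    stats::rbinom(length(lv), design$n_per_level, latent) /
      design$n_per_level
  ds <- deb_dataset("diapause_moisture", "diapause_fraction", lv, obs,
                    scenario = list())
  list(observation_set = observation_set(datasets = list(ds)),
       latent = list(diapause_moisture = latent))
}

gen_weight_moisture <- function(design, params, control) {
  sc <- list(T_C = 20, OM = 4, duration = design$duration,
             initial = "juvenile",
             L_0 = (0.048 / (1 + params$w))^(1 / 3))
  reg <- observable_registry()
  latent <- reg$fresh_weight_vs_moisture(design$levels, sc, params,
                                         control, NULL)
  x <- rep(design$levels, each = design$n_per_level)
  obs <- lognormal_noise(rep(latent, each = design$n_per_level), design$cv)
  ds <- deb_dataset("weight_moisture", "fresh_weight_vs_moisture", x, obs,
                    scenario = sc)
  list(observation_set = observation_set(datasets = list(ds)),
       latent = list(weight_moisture = latent))
}

gen_growth_food <- function(design, params, control, observable) {
  reg <- observable_registry()
  ds <- list(); latent <- list()
  L_0 <- (0.05 / (1 + params$w))^(1 / 3)
  for (f in design$levels) {
    sc <- list(T_C = 20, f = f, initial = "juvenile", L_0 = L_0)
    lat <- reg[[observable]](design$sampling_times, sc, params, control,
                             NULL)
    x <- rep(design$sampling_times, each = design$n_per_level)
    obs <- lognormal_noise(rep(lat, each = design$n_per_level), design$cv)
    nm <- paste0("growth_f", f)
    ds[[nm]] <- deb_dataset(nm, observable, x, obs, scenario = sc)
    latent[[nm]] <- lat
  }
  list(observation_set = observation_set(datasets = unname(ds)),
       latent = latent)
}

gen_reproduction_food <- function(design, params, control) {
  reg <- observable_registry()
  ds <- list(); latent <- list()
  L_0 <- (0.05 / (1 + params$w))^(1 / 3)
  for (lev in design$levels) {
    sc <- list(T_C = 20, f = lev[["f"]], f_adult = lev[["f_adult"]],
               initial = "juvenile", L_0 = L_0)
    lat <- reg$eggs_cum(design$sampling_times, sc, params, control, NULL)
    x <- rep(design$sampling_times, each = design$n_per_level)
    obs <- lognormal_noise(rep(lat, each = design$n_per_level), design$cv)
    nm <- paste0("repro_f", lev[["f"]], "_", lev[["f_adult"]])
    ds[[nm]] <- deb_dataset(nm, "eggs_cum", x, obs, scenario = sc)
    latent[[nm]] <- lat
  }
  list(observation_set = observation_set(datasets = unname(ds)),
       latent = latent)
}

#' Parameter-recovery study
#'
#' Repeated generate-then-refit cycles: for each replicate, synthetic data
#' are generated from the true parameters under one or more designs, the
#' free parameters are re-estimated, and the estimates collected. Reports
#' bias, relative RMSE and coverage of a +/-10\% band around the truth.
#'
#' @param designs an [experiment_design()] or a list of them; all datasets
#'   of a replicate are fitted jointly
#' @param params generating (true) [deb_params()]
#' @param free parameter names to re-estimate
#' @param n_replicates number of replicates (>= 2)
#' @param seed study seed; replicate r uses design seeds derived from
#'   `seed` and `r`
#' @param start_params starting values for each fit (defaults to the truth)
#' @param config a [fit_control()]
#' @param control a [deb_control()]
#' @return list of class `recovery_study` with `estimates` (data.frame,
#'   one row per replicate x parameter), `summary` (data.frame with `true`,
#'   `median`, `bias`, `rel_rmse`, `coverage_10pct` per parameter) and
#'   `n_failed`
#' @export
recovery_study <- function(designs, params = deb_params(), free,
                           n_replicates = 50, seed = 1,
                           start_params = params,
                           config = fit_control(),
                           control = deb_control()) {
  if (inherits(designs, "experiment_design")) designs <- list(designs)
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  rows <- list(); n_failed <- 0
  for (r in seq_len(n_replicates)) {
    all_ds <- list()
    ok <- TRUE
    for (j in seq_along(designs)) {
      d <- designs[[j]]
      d$seed <- (seed + 7919L * r + 104729L * j) %% .Machine$integer.max
      syn <- tryCatch(generate_experiment(d, params, control),
                      error = function(e) NULL)
      if (is.null(syn)) { ok <- FALSE; break }
      all_ds <- c(all_ds, syn$observation_set$datasets)
    }
    fit <- if (ok)
      tryCatch(fit_deb(observation_set(datasets = all_ds), start_params,
                       free, config, control),
               error = function(e) NULL)
    else NULL
    if (is.null(fit)) { n_failed <- n_failed + 1; next }
    rows[[length(rows) + 1]] <- data.frame(
      replicate = r, parameter = free,
      estimate = unlist(fit$params[free]), true = unlist(params[free]),
      loss = fit$loss, row.names = NULL)
  }
  if (n_failed > n_replicates / 2)
    stop("more than half of the replicate fits failed (", n_failed, "/",
         n_replicates, ")")
  est <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(free, function(pn) {
    e <- est[est$parameter == pn, ]
    tv <- e$true[1]
    data.frame(parameter = pn, true = tv,
               median = stats::median(e$estimate),
               bias = mean(e$estimate) - tv,
               rel_rmse = sqrt(mean((e$estimate - tv)^2)) / abs(tv),
               coverage_10pct = mean(abs(e$estimate - tv) <= 0.1 * abs(tv)))
  }))
  structure(list(estimates = est, summary = summ, n_failed = n_failed,
                 free = free, seed = seed),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat("<recovery_study> ", length(unique(x$estimates$replicate)),
      " successful replicates (", x$n_failed, " failed)\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}
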