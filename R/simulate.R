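#' Integrator and embryo-delay settings
#'
#' @param rtol,atol relative and absolute integrator tolerances
#' @param t0_temperature_corrected should the cocoon pre-development delay
#'   `t_0` be temperature-corrected (divided by `F_t`)? Development time
#'   data shrink as a whole with temperature, so the default is `TRUE`.
#' @param L_seed embryo seed structural length (cm)
#' @param max_embryo_days cap on the embryo integration window (d)
#' @return list of class `deb_control`
#' @export
deb_control <- function(rtol = 1e-8, atol = 1e-10,
                        t0_temperature_corrected = TRUE,
                        L_seed = 1e-4, max_embryo_days = 2000) {
  structure(list(rtol = rtol, atol = atol,
                 t0_temperature_corrected = t0_temperature_corrected,
                 L_seed = L_seed, max_embryo_days = max_embryo_days),
            class = "deb_control")
}

#' Simulation scenario
#'
#' Describes one individual-level simulation: the environmental forcing, the
#' initial state, the duration, and (optionally) an imposed feeding level
#' replacing the environment-derived `f_OM * f_M`.
#'
#' @param environment a [deb_environment()]
#' @param duration simulation length (d)
#' @param initial one of `"egg"`, `"juvenile"`, `"adult"`
#' @param L_0 initial structural length (cm); required for juvenile/adult
#' @param e_0 initial scaled reserve density (default 1)
#' @param f optional imposed feeding level (scalar); overrides the
#'   environment-derived functional responses (embryos do not feed either way)
#' @param f_adult optional feeding level applied from puberty onwards (the
#'   pairing scenario: grouped worms feed at a lower level than individuals)
#' @param gut_content constant gut content mass (g) added to reported fresh
#'   weight
#' @param times output time grid (d); default 201 equally spaced points
#' @return object of class `deb_scenario`
#' @examples
#' sc <- deb_scenario(deb_environment(T_C = 19.95), duration = 100,
#'                    initial = "juvenile", L_0 = 0.1, f = 1)
#' @export
deb_scenario <- function(environment = deb_environment(), duration,
                         initial = c("egg", "juvenile", "adult"),
                         L_0 = NULL, e_0 = 1, f = NULL, f_adult = NULL,
                         gut_content = 0, times = NULL) {
  initial <- match.arg(initial)
  if (duration <= 0) stop("duration must be positive")
  if (initial != "egg" && (is.null(L_0) || L_0 <= 0))
    stop("initial state '", initial, "' requires a positive L_0")
  if (!is.null(f) && f < 0) stop("feeding level f must be >= 0")
  if (is.null(times)) times <- seq(0, duration, length.out = 201)
  if (any(times < 0 | times > duration)) stop("times must lie in [0, duration]")
  structure(list(environment = environment, duration = duration,
                 initial = initial, L_0 = L_0, e_0 = e_0, f = f,
                 f_adult = f_adult, gut_content = gut_content,
                 times = sort(unique(c(0, times, duration)))),
            class = "deb_scenario")
}

# RHS shared by all life-cycle phases. y = (L, E, EH, ER); feeding and the
# maturity/reproduction switch are fixed per phase.
deb_rhs <- function(t, y, parms) {
  pp <- parms$params
  L <- y[[1]]; E <- max(y[[2]], 0); EH <- y[[3]]
  F_t <- temperature_correction(parms$env$T_C(t), pp)
  p_A <- if (parms$embryo) {
    0
  } else if (!is.null(parms$f)) {
    F_t * parms$f * pp$p_am * L^2
  } else {
    f_OM <- om_functional_response(parms$env$OM(t), L, pp)$f_OM
    f_M <- moisture_functional_response(parms$env$M(t), pp)
    F_t * f_OM * f_M * pp$p_am * L^2
  }
  r <- (E * F_t * pp$v / L^4 - F_t * pp$p_M / pp$kappa) /
    (E / L^3 + pp$E_G / pp$kappa)
  p_C <- E * (F_t * pp$v / L - r)
  p_J <- F_t * pp$k_J * min(EH, pp$EH_p)
  net <- max(0, (1 - pp$kappa) * p_C - p_J)
  list(c(max(0, r) / 3 * L,
         p_A - p_C,
         if (parms$adult) 0 else net,
         if (parms$adult) pp$kappa_R * net else 0))
}

integrate_phase <- function(y0, t_from, t_to, out_times, parms, root_EH,
                            control) {
  times <- sort(unique(c(t_from, out_times[out_times > t_from & out_times <= t_to],
                         t_to)))
  rootfunc <- if (is.null(root_EH)) NULL else
    function(t, y, parms) y[[3]] - root_EH
  out <- deSolve::lsoda(y0, times, deb_rhs, parms, rtol = control$rtol,
                        atol = control$atol, rootfunc = rootfunc)
  if (attr(out, "istate")[1] < 0)
    stop("integration failed at t = ", max(out[, 1]),
         "; last state: L = ", signif(out[nrow(out), 2], 6),
         ", E = ", signif(out[nrow(out), 3], 6))
  troot <- attr(out, "troot")
  list(out = out, troot = if (length(troot)) troot[1] else NULL)
}

#' Simulate the full life cycle
#'
#' Integrates the reserve/structure/maturity/reproduction system under a
#' forcing scenario, locating the birth (`E_H = EH_b`) and puberty
#' (`E_H = EH_p`) transitions by event detection. Embryos do not feed; when
#' the scenario starts from an egg, the cocoon pre-development delay `t_0`
#' precedes integration (temperature-corrected by default, see
#' [deb_control()]). All rate constants are temperature-corrected at every
#' time step.
#'
#' @param scenario a [deb_scenario()]
#' @param params a [deb_params()]
#' @param control a [deb_control()]
#' @return object of class `deb_trajectory`: a list with
#'   \describe{
#'     \item{states}{data.frame of time (d), stage, `L_cm`, `E_J`, `EH_J`,
#'       `ER_J`, scaled reserve density `e`, physical length `Lw_cm`, dry
#'       weight `Wd_g`, fresh weight `Ww_g`, cumulative egg equivalents
#'       `eggs_cum`, `cast_g_per_d`, `burrow_cm_per_d`}
#'     \item{events}{list with `age_at_birth`, `age_at_puberty`,
#'       `time_since_birth_at_puberty` (d; `NA` when not reached/applicable)}
#'     \item{scenario, params, control}{the inputs}
#'   }
#' @examples
#' sc <- deb_scenario(deb_environment(T_C = 19.95, M = 20, OM = 4),
#'                    duration = 50, initial = "juvenile", L_0 = 0.1, f = 1)
#' traj <- simulate_deb(sc, deb_params())
#' tail(traj$states$Ww_g, 1)
#' @export
simulate_deb <- function(scenario, params = deb_params(),
                         control = deb_control()) {
  env <- scenario$environment
  out_times <- scenario$times
  dur <- scenario$duration
  t_birth <- NA_real_; t_puberty <- NA_real_
  rows <- list()
  base_parms <- list(params = params, env = env, f = scenario$f,
                     embryo = FALSE, adult = FALSE)

  t_cur <- 0
  if (scenario$initial == "egg") {
    egg <- initial_egg_state(params, control$L_seed)
    y <- c(L = egg$L, E = egg$E, EH = 0, ER = 0)
    lag <- params$t_0
    if (control$t0_temperature_corrected)
      lag <- lag / temperature_correction(env$T_C(0), params)
    # dormant pre-development phase: state frozen
    lag_t <- out_times[out_times < min(lag, dur)]
    rows[[length(rows) + 1]] <-
      cbind(time = c(lag_t, min(lag, dur)),
            matrix(y, nrow = length(lag_t) + 1, ncol = 4, byrow = TRUE,
                   dimnames = list(NULL, names(y))))
    t_cur <- min(lag, dur)
    if (t_cur < dur) {
      parms <- base_parms; parms$embryo <- TRUE
      ph <- integrate_phase(y, t_cur, dur, out_times, parms, params$EH_b,
                            control)
      rows[[length(rows) + 1]] <- ph$out
      if (!is.null(ph$troot)) {
        t_birth <- ph$troot
        y <- ph$out[nrow(ph$out), 2:5]
        t_cur <- t_birth
      } else t_cur <- dur
    }
  } else if (scenario$initial == "juvenile") {
    y <- c(L = scenario$L_0,
           E = scenario$e_0 * params$p_am / params$v * scenario$L_0^3,
           EH = params$EH_b, ER = 0)
    t_birth <- 0
  } else {
    y <- c(L = scenario$L_0,
           E = scenario$e_0 * params$p_am / params$v * scenario$L_0^3,
           EH = params$EH_p, ER = 0)
    t_puberty <- 0
  }

  if (t_cur < dur && !is.na(t_birth) && is.na(t_puberty)) {
    parms <- base_parms
    ph <- integrate_phase(y, t_cur, dur, out_times, parms, params$EH_p,
                          control)
    rows[[length(rows) + 1]] <- ph$out
    if (!is.null(ph$troot)) {
      t_puberty <- ph$troot
      y <- ph$out[nrow(ph$out), 2:5]
      t_cur <- t_puberty
    } else t_cur <- dur
  }
  if (t_cur < dur && !is.na(t_puberty)) {
    parms <- base_parms; parms$adult <- TRUE
    if (!is.null(scenario$f_adult)) parms$f <- scenario$f_adult
    y[["EH"]] <- params$EH_p
    ph <- integrate_phase(y, t_cur, dur, out_times, parms, NULL, control)
    rows[[length(rows) + 1]] <- ph$out
  }

  st <- do.call(rbind, lapply(rows, function(m) as.data.frame(unclass(m))[1:5]))
  names(st) <- c("time", "L", "E", "EH", "ER")
  st <- st[!duplicated(st$time, fromLast = TRUE), , drop = FALSE]
  st <- st[order(st$time), , drop = FALSE]
  st$E <- pmax(st$E, 0)
  traj <- build_trajectory(st, scenario, params)
  traj$events <- list(
    age_at_birth = t_birth,
    age_at_puberty = t_puberty,
    time_since_birth_at_puberty =
      if (!is.na(t_birth) && !is.na(t_puberty)) t_puberty - t_birth
      else NA_real_)
  traj
}

build_trajectory <- function(st, scenario, params) {
  env <- scenario$environment
  e <- scaled_reserve_density(st$E, st$L, params)
  stage <- ifelse(st$EH < params$EH_b, "embryo",
                  ifelse(st$EH < params$EH_p, "juvenile", "adult"))
  F_t <- temperature_correction(env$T_C(st$time), params)
  OM <- env$OM(st$time); M <- env$M(st$time)
  cast <- ifelse(OM > 0 & stage != "embryo",
                 F_t * om_functional_response(pmax(OM, 1e-12), st$L,
                                              params)$p_X /
                   (params$mu_OM * pmax(OM, 1e-12)),
                 0)
  states <- data.frame(
    time = st$time, stage = stage, L_cm = st$L, E_J = st$E, EH_J = st$EH,
    ER_J = st$ER, e = e,
    Lw_cm = physical_length(st$L, params),
    Wd_g = dry_weight(st$L, e, params),
    Ww_g = fresh_weight(st$L, e, params, scenario$gut_content),
    eggs_cum = eggs_from_buffer(st$ER, params),
    cast_g_per_d = cast,
    burrow_cm_per_d = ifelse(stage == "embryo", 0,
                             burrow_rate(M, st$L, params, F_t)))
  structure(list(states = states, events = NULL, scenario = scenario,
                 params = params),
            class = "deb_trajectory")
}

#' @export
print.deb_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat("<deb_trajectory> ", n, " time points over ",
      format(max(x$states$time)), " d\n", sep = "")
  ev <- x$events
  if (!is.null(ev))
    cat("  age at birth: ", format(ev$age_at_birth),
        " d; age at puberty: ", format(ev$age_at_puberty), " d\n", sep = "")
  print(utils::head(x$states, 3), ...)
  cat("  ...\n")
  print(utils::tail(x$states, 2), ...)
  invisible(x)
}

#' Egg equivalents in the reproduction buffer
#'
#' `Eggs = E_R / (U_E0 p_am)`: the reproduction buffer divided by the energy
#' cost of one egg.
#'
#' @param E_R reproduction buffer (J); vectorized
#' @param params a [deb_params()]
#' @param integer if `TRUE`, return the floor-integer clutch count instead
#'   of the continuous expected count
#' @return egg count (continuous by default)
#' @export
eggs_from_buffer <- function(E_R, params, integer = FALSE) {
  if (any(E_R < 0)) stop("E_R must be non-negative")
  eggs <- E_R / (params$U_E0 * params$p_am)
  if (integer) floor(eggs) else eggs
}

#' Physical (measured) length
#'
#' `L_w = L / delta_M`.
#' @param L structural length (cm)
#' @param params a [deb_params()]
#' @return physical length (cm)
#' @export
physical_length <- function(L, params) {
  if (any(L < 0)) stop("L must be non-negative")
  L / params$delta_M
}

#' Dry weight
#'
#' `W_d = L^3 delta_V (1 + w e)`, with `e` the instantaneous scaled reserve
#' density standing in for the feeding level (they coincide at feeding
#' equilibrium).
#'
#' @param L structural length (cm)
#' @param e scaled reserve density
#' @param params a [deb_params()]
#' @return dry weight (g)
#' @export
dry_weight <- function(L, e, params) {
  if (any(L < 0) || any(e < 0)) stop("L and e must be non-negative")
  L^3 * params$delta_V * (1 + params$w * e)
}

#' Fresh weight with water replacement
#'
#' `W_w = L^3 (1 + w e + w_V (1 - min(e, 1))) + gut_content`: under reserve
#' depletion the freed reserve volume is partly replaced by water, damping
#' the apparent weight loss. At `e = 1` this reduces to `L^3 (1 + w)`.
#'
#' @inheritParams dry_weight
#' @param gut_content constant gut content mass (g)
#' @return fresh weight (g)
#' @export
fresh_weight <- function(L, e, params, gut_content = 0) {
  if (any(L < 0) || any(e < 0)) stop("L and e must be non-negative")
  L^3 * (1 + params$w * e + params$w_V * (1 - pmin(e, 1))) + gut_content
}

#' Summarize a set of trajectories
#'
#' Mean and standard deviation of every observable across trajectories
#' sharing a common time grid. Burrow-rate summaries are weighted by the
#' moving fraction `1 - D` (diapausing worms do not burrow).
#'
#' @param trajectories list of [simulate_deb()] results on the same grid
#' @param D diapausing fraction applied to burrow-rate summaries (default 0)
#' @return data.frame with time and `<observable>_mean` / `<observable>_sd`
#'   columns
#' @export
population_summary <- function(trajectories, D = 0) {
  if (length(trajectories) == 0) stop("empty trajectory set")
  if (D < 0 || D > 1) stop("D must lie in [0, 1]")
  obs <- c("L_cm", "Lw_cm", "Wd_g", "Ww_g", "eggs_cum", "cast_g_per_d",
           "burrow_cm_per_d")
  tgrid <- trajectories[[1]]$states$time
  for (tr in trajectories)
    if (!isTRUE(all.equal(tr$states$time, tgrid)))
      stop("trajectories must share a common time grid")
  out <- data.frame(time = tgrid)
  for (v in obs) {
    m <- sapply(trajectories, function(tr) tr$states[[v]])
    m <- matrix(m, nrow = length(tgrid))
    if (v == "burrow_cm_per_d") m <- m * (1 - D)
    out[[paste0(v, "_mean")]] <- rowMeans(m)
    out[[paste0(v, "_sd")]] <- apply(m, 1, stats::sd)
    if (length(trajectories) == 1) out[[paste0(v, "_sd")]] <- 0
  }
  out
}

#' Export a trajectory as delimited text
#'
#' @param traj a `deb_trajectory`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj$states, path, row.names = FALSE)
  invisible(path)
}
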