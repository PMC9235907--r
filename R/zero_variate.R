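#' Zero-variate life-history predictions
#'
#' Computes the six single-number life-history predictions used for
#' parameterization, at feeding level `f = 1`: time since birth at puberty
#' (d), physical length at birth (cm), ultimate total length (cm), fresh
#' weight at birth (g), fresh weight at puberty (g) and ultimate fresh
#' weight (g).
#'
#' Lengths and weights are temperature-invariant (temperature rescales time
#' only). The time from birth to puberty is a duration and therefore depends
#' on temperature: it is reported at `temp_C_tp`, which defaults to 15 deg C,
#' the standard husbandry temperature of the laboratory growth studies such
#' observations come from. The juvenile phase is integrated at reference
#' temperature and the elapsed time rescaled by `1 / F_t(temp_C_tp)` (exact,
#' because all rates share one temperature correction).
#'
#' The ultimate structural length is the fixed point of the growth equation,
#' `L_inf = kappa p_am / p_M`, evaluated in closed form.
#'
#' @param params a [deb_params()]
#' @param temp_C_tp temperature (deg C) at which the time from birth to
#'   puberty is reported
#' @param control a [deb_control()]
#' @param max_days cap on the birth-to-puberty integration (d) at reference
#'   temperature; failure to reach puberty within it is an error
#' @return named numeric vector with elements
#'   `time_since_birth_at_puberty`, `length_at_birth`, `ultimate_length`,
#'   `fresh_weight_at_birth`, `fresh_weight_at_puberty`,
#'   `ultimate_fresh_weight`; structural lengths at birth/puberty and the
#'   embryo integration time are attached as attribute `"details"`.
#' @examples
#' round(predict_zero_variate(deb_params()), 3)
#' @export
predict_zero_variate <- function(params = deb_params(), temp_C_tp = 15,
                                 control = deb_control(), max_days = 1000) {
  T_ref_C <- params$T_ref - 273.15   # F_t = 1 exactly
  env <- deb_environment(T_C = T_ref_C, M = 20, OM = 4)

  emb <- simulate_deb(
    deb_scenario(env, duration = control$max_embryo_days, initial = "egg",
                 f = 1),
    params, control)
  if (is.na(emb$events$age_at_birth))
    stop("embryo failed to reach birth maturity within ",
         control$max_embryo_days, " d")
  i_b <- which.min(abs(emb$states$time - emb$events$age_at_birth))
  L_b <- emb$states$L_cm[i_b]
  t_embryo <- emb$events$age_at_birth -
    (params$t_0 / temperature_correction(T_ref_C, params))

  juv <- simulate_deb(
    deb_scenario(env, duration = max_days, initial = "juvenile",
                 L_0 = L_b, e_0 = 1, f = 1),
    params, control)
  tp_ref <- juv$events$time_since_birth_at_puberty
  if (is.na(tp_ref))
    stop("puberty not reached within ", max_days, " d at f = 1")
  i_p <- which.min(abs(juv$states$time - juv$events$age_at_puberty))
  L_p <- juv$states$L_cm[i_p]

  L_inf <- params$kappa * params$p_am / params$p_M
  F_tp <- temperature_correction(temp_C_tp, params)

  out <- c(
    time_since_birth_at_puberty = tp_ref / F_tp,
    length_at_birth = physical_length(L_b, params),
    ultimate_length = physical_length(L_inf, params),
    fresh_weight_at_birth = fresh_weight(L_b, 1, params),
    fresh_weight_at_puberty = fresh_weight(L_p, 1, params),
    ultimate_fresh_weight = fresh_weight(L_inf, 1, params))
  attr(out, "details") <- list(L_b = L_b, L_p = L_p, L_inf = L_inf,
                               t_embryo = t_embryo, tp_ref = tp_ref,
                               temp_C_tp = temp_C_tp)
  out
}
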