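#' Environmental forcing scenario
#'
#' Bundle the three environmental drivers — ambient temperature (deg C),
#' soil moisture (% water content) and organic matter content (% of soil
#' mass) — as constants or time-tabulated series with linear interpolation.
#'
#' @param T_C temperature: a single value or a data.frame-compatible pair;
#'   if `table` is given, constants are ignored for tabulated columns
#' @param M moisture content (\%)
#' @param OM organic matter content (\%)
#' @param table optional data.frame with column `time_d` and any of
#'   `T_C`, `moisture_pct`, `om_pct`; tabulated columns are linearly
#'   interpolated (constant extrapolation beyond the table range)
#' @return object of class `deb_environment`: list of functions `T_C(t)`,
#'   `M(t)`, `OM(t)`
#' @examples
#' env <- deb_environment(T_C = 20, M = 20, OM = 4)
#' env$M(10)
#' @export
deb_environment <- function(T_C = 20, M = 20, OM = 4, table = NULL) {
  mk <- function(const, col) {
    if (!is.null(table) && col %in% names(table)) {
      if (!"time_d" %in% names(table))
        stop("forcing table must have a 'time_d' column")
      stats::approxfun(table$time_d, table[[col]], rule = 2)
    } else {
      force(const)
      function(t) rep_len(const, length(t))
    }
  }
  env <- structure(list(T_C = mk(T_C, "T_C"), M = mk(M, "moisture_pct"),
                        OM = mk(OM, "om_pct")),
                   class = "deb_environment")
  chk <- function(x, lo, hi, what)
    if (any(x < lo | x > hi)) stop(what, " outside sanity bounds [",
                                   lo, ", ", hi, "]")
  t0 <- if (is.null(table)) 0 else table$time_d
  chk(env$T_C(t0), -50, 60, "temperature")
  chk(env$M(t0), 0, Inf, "moisture")
  chk(env$OM(t0), 0, Inf, "organic matter")
  env
}

#' Arrhenius temperature correction with upper boundary
#'
#' Correction factor applied to every physiological rate constant. Below the
#' reference temperature the factor follows the one-parameter Arrhenius
#' relation `s_A = exp(T_A / T_ref - T_A / (T + 273.15))`; at and above
#' `T_ref` it is multiplied by the upper-boundary correction
#' `s_rH = (1 + exp(T_AH/T_H - T_AH/T_ref)) / (1 + exp(T_AH/T_H - T_AH/(T+273.15)))`,
#' which makes the response unimodal with an interior maximum near `T_H`.
#' Continuous at `T_ref` (where the factor equals 1).
#'
#' @param T_C ambient temperature (deg C); vectorized
#' @param params a [deb_params()] object
#' @return temperature correction factor(s), > 0
#' @examples
#' temperature_correction(deb_params()$T_ref - 273.15, deb_params())  # 1
#' @export
temperature_correction <- function(T_C, params) {
  TK <- T_C + 273.15
  if (any(TK <= 0)) stop("temperature below absolute zero")
  s_A <- exp(params$T_A / params$T_ref - params$T_A / TK)
  # log1p(exp(x)) computed stably for large x
  l1pe <- function(x) ifelse(x > 35, x, log1p(exp(x)))
  a_ref <- params$T_AH / params$T_H - params$T_AH / params$T_ref
  a_T <- params$T_AH / params$T_H - params$T_AH / TK
  s_rH <- exp(l1pe(a_ref) - l1pe(a_T))
  ifelse(TK >= params$T_ref, s_A * s_rH, s_A)
}

#' Organic-matter functional response
#'
#' Food availability is coupled to soil organic matter through the energy
#' density `X = mu_OM * OM` (J per g of soil) and a Holling type-II
#' saturating uptake with half-saturation `x_K = p_am / F_m`:
#' `p_OM = p_am L^2 X / (x_K + X)`. The ingestion-energy flux is
#' `p_X = p_OM / kappa_X`, and the scaled functional response is
#' `f_OM = p_OM / (p_am L^2)`, bounded in \[0, 1\] so that `p_am` remains
#' the maximum assimilation flux.
#'
#' @param OM organic matter content (\%), >= 0; vectorized
#' @param L structural length (cm), > 0
#' @param params a [deb_params()] object
#' @return list with `p_OM` (J d^-1), `p_X` (J d^-1), `f_OM` (-), and the
#'   intermediates `X`, `x_K` (J g^-1); fluxes are at reference temperature
#' @examples
#' om_functional_response(4, 0.3, deb_params())$f_OM
#' @export
om_functional_response <- function(OM, L, params) {
  if (any(OM < 0)) stop("organic matter content must be non-negative")
  if (any(L <= 0)) stop("L must be positive")
  X <- params$mu_OM * OM
  x_K <- params$p_am / params$F_m
  f_OM <- X / (x_K + X)
  p_OM <- params$p_am * L^2 * f_OM
  list(p_OM = p_OM, p_X = p_OM / params$kappa_X, f_OM = f_OM,
       X = X, x_K = x_K)
}

#' Cast production (soil ingestion) rate
#'
#' Cast weight equals the ingested soil mass: the ingestion-energy flux
#' `p_X` divided by the energy content per gram of soil `mu_OM * OM`,
#' temperature-corrected. Assimilated energy is assumed to contribute
#' negligibly to cast weight.
#'
#' @inheritParams om_functional_response
#' @param T_C ambient temperature (deg C)
#' @return soil ingestion / cast production rate (g d^-1)
#' @export
cast_production_rate <- function(OM, L, T_C, params) {
  if (any(OM <= 0)) stop("cast production undefined at zero organic matter")
  F_t <- temperature_correction(T_C, params)
  omr <- om_functional_response(OM, L, params)
  F_t * omr$p_X / (params$mu_OM * OM)
}

#' Burrow rate
#'
#' Threshold-linear moisture response of movement:
#' `B = F_t k_b L^2 max(0, M - m_0)`. Below the moisture threshold `m_0`
#' the worms do not burrow.
#'
#' @param M moisture content (\%), >= 0; vectorized
#' @param L structural length (cm), > 0
#' @param params a [deb_params()] object
#' @param F_t temperature correction factor
#' @return burrow rate (cm d^-1)
#' @export
burrow_rate <- function(M, L, params, F_t = 1) {
  if (any(M < 0)) stop("moisture content must be non-negative")
  if (any(L <= 0)) stop("L must be positive")
  F_t * params$k_b * L^2 * pmax(0, M - params$m_0)
}

#' Fraction of diapausing worms
#'
#' Probability that a worm is in diapause (quiescence) at moisture `M`:
#' `D = exp(-b_w max(0, M - m_0))`. Equals 1 at and below the movement
#' threshold `m_0` and decreases exponentially above it.
#'
#' @inheritParams burrow_rate
#' @return diapausing fraction in (0, 1]
#' @export
diapause_fraction <- function(M, params) {
  if (any(M < 0)) stop("moisture content must be non-negative")
  exp(-params$b_w * pmax(0, M - params$m_0))
}

#' Moisture functional response
#'
#' The burrow rate scaled by the maximum surface-area-specific rate:
#' `f_M = min(1, k_b max(0, M - m_0) / b_max)`. Zero at/below the threshold,
#' rising linearly, saturating at 1 (so that `p_am` remains the maximum
#' assimilation flux).
#'
#' @inheritParams burrow_rate
#' @return scaled functional response in \[0, 1\]
#' @export
moisture_functional_response <- function(M, params) {
  if (any(M < 0)) stop("moisture content must be non-negative")
  pmin(1, params$k_b * pmax(0, M - params$m_0) / params$b_max)
}

#' Assimilation flux
#'
#' `p_A = F_t f_OM f_M p_am L^2`: the two scaled functional responses are
#' multiplied. An `f_override` replaces the product `f_OM * f_M` for
#' scenarios where the feeding level is imposed directly (it may exceed 1,
#' as estimated for ad-libitum-fed individually kept worms).
#'
#' @param f_OM,f_M scaled functional responses in \[0, 1\]
#' @param L structural length (cm)
#' @param params a [deb_params()] object
#' @param F_t temperature correction factor
#' @param f_override optional scalar feeding level replacing `f_OM * f_M`
#' @return assimilation flux (J d^-1)
#' @export
assimilation_flux <- function(f_OM, f_M, L, params, F_t = 1,
                              f_override = NULL) {
  if (!is.null(f_override)) {
    if (any(f_override < 0)) stop("feeding level override must be >= 0")
    f <- f_override
  } else {
    if (any(f_OM < 0 | f_OM > 1) || any(f_M < 0 | f_M > 1))
      stop("scaled functional responses must lie in [0, 1]")
    f <- f_OM * f_M
  }
  F_t * f * params$p_am * L^2
}

#' Forcing outputs at given environmental conditions
#'
#' Convenience wrapper evaluating all environmental response functions at
#' once for a worm of structural length `L`.
#'
#' @param T_C temperature (deg C)
#' @param M moisture (\%)
#' @param OM organic matter (\%)
#' @param L structural length (cm)
#' @param params a [deb_params()] object
#' @return list with `F_t`, `f_OM`, `f_M`, `D`, `B` (cm d^-1), `p_OM`,
#'   `p_X`, `p_A` (J d^-1), `J_x` (g d^-1; `NA` when `OM = 0`)
#' @export
forcing_outputs <- function(T_C, M, OM, L, params) {
  F_t <- temperature_correction(T_C, params)
  omr <- om_functional_response(OM, L, params)
  f_M <- moisture_functional_response(M, params)
  list(F_t = F_t, f_OM = omr$f_OM, f_M = f_M,
       D = diapause_fraction(M, params),
       B = burrow_rate(M, L, params, F_t),
       p_OM = F_t * omr$p_OM, p_X = F_t * omr$p_X,
       p_A = assimilation_flux(omr$f_OM, f_M, L, params, F_t),
       J_x = ifelse(OM > 0, F_t * omr$p_X / (params$mu_OM * OM), NA_real_),
       X = omr$X, x_K = omr$x_K)
}
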