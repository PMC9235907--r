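#' Organism state
#'
#' The four primary DEB state variables plus the life stage. The stage is
#' derived from maturity: embryo while `E_H < EH_b`, adult once
#' `E_H >= EH_p`, juvenile in between.
#'
#' @param L volumetric structural length (cm), > 0
#' @param E reserve energy (J), >= 0
#' @param E_H maturity level (J), >= 0
#' @param E_R reproduction buffer (J), >= 0 (zero before puberty)
#' @param params a [deb_params()] object (used to classify the stage)
#' @return An object of class `organism_state` with fields `L`, `E`, `E_H`,
#'   `E_R` and `stage`.
#' @examples
#' organism_state(L = 0.2, E = 50, E_H = 100, E_R = 0, params = deb_params())
#' @export
organism_state <- function(L, E, E_H, E_R = 0, params = deb_params()) {
  if (!is.finite(L) || L <= 0) stop("structural length L must be positive")
  if (E < 0) stop("reserve E must be non-negative")
  if (E_H < 0) stop("maturity E_H must be non-negative")
  if (E_R < 0) stop("reproduction buffer E_R must be non-negative")
  stage <- life_stage(E_H, params)
  if (E_R > 0 && stage != "adult")
    stop("reproduction buffer must be zero before puberty")
  structure(list(L = L, E = E, E_H = min(E_H, params$EH_p), E_R = E_R,
                 stage = stage),
            class = "organism_state")
}

life_stage <- function(E_H, params) {
  if (E_H < params$EH_b) "embryo"
  else if (E_H < params$EH_p) "juvenile"
  else "adult"
}

#' Specific growth rate
#'
#' The specific growth rate of structure,
#' `r = (E v L^-4 - p_M / kappa) / (E L^-3 + E_G / kappa)`,
#' with the rate constants `v` and `p_M` multiplied by the temperature
#' correction factor `F_t`. `r` may be negative when reserve cannot cover
#' somatic maintenance (down to the starvation limit `-p_M/E_G` at `E = 0`);
#' structure itself does not shrink (see [state_derivatives()]).
#'
#' @param E reserve energy (J)
#' @param L structural length (cm), > 0
#' @param params a [deb_params()] object
#' @param F_t temperature correction factor (default 1, i.e. at `T_ref`)
#' @return specific growth rate (d^-1)
#' @examples
#' p <- deb_params()
#' L_inf <- p$kappa * p$p_am / p$p_M
#' specific_growth_rate(E = p$p_am / p$v * L_inf^3, L = L_inf, params = p)  # ~0
#' @export
specific_growth_rate <- function(E, L, params, F_t = 1) {
  if (!all(is.finite(L)) || any(L <= 0)) stop("L must be positive")
  if (any(E < 0)) stop("E must be non-negative")
  if (any(F_t <= 0)) stop("F_t must be positive")
  (E * F_t * params$v / L^4 - F_t * params$p_M / params$kappa) /
    (E / L^3 + params$E_G / params$kappa)
}

#' Mobilization flux
#'
#' Reserve mobilization `p_C = E (F_t v / L - r)`, the flux leaving the
#' reserve to fuel all metabolic work.
#'
#' @inheritParams specific_growth_rate
#' @param r specific growth rate (d^-1), from [specific_growth_rate()]
#' @return mobilization flux (J d^-1)
#' @export
mobilization_flux <- function(E, L, r, params, F_t = 1) {
  if (!all(is.finite(L)) || any(L <= 0)) stop("L must be positive")
  E * (F_t * params$v / L - r)
}

#' Maturity maintenance flux
#'
#' `p_J = F_t k_J min(E_H, EH_p)`: maintenance of the attained maturity
#' level, capped at the puberty threshold (maturity is frozen at `EH_p` in
#' adults).
#'
#' @param E_H maturity level (J)
#' @inheritParams specific_growth_rate
#' @return maturity maintenance flux (J d^-1)
#' @export
maturity_maintenance <- function(E_H, params, F_t = 1) {
  if (any(E_H < 0)) stop("E_H must be non-negative")
  F_t * params$k_J * pmin(E_H, params$EH_p)
}

#' Energy fluxes at a state
#'
#' Evaluate assimilation-independent fluxes (`r`, `p_C`, `p_J`) at a state.
#'
#' @param state an [organism_state()]
#' @inheritParams specific_growth_rate
#' @return list with `r`, `p_C`, `p_J`
#' @export
deb_fluxes <- function(state, params, F_t = 1) {
  r <- specific_growth_rate(state$E, state$L, params, F_t)
  list(r = r,
       p_C = mobilization_flux(state$E, state$L, r, params, F_t),
       p_J = maturity_maintenance(state$E_H, params, F_t))
}

#' State derivatives of the DEB system
#'
#' Right-hand side of the coupled reserve/structure/maturity/reproduction
#' system: `dE/dt = p_A - p_C`, `dL/dt = max(0, r)/3 L` (no structural
#' shrinking; weight loss is carried by reserve depletion and water
#' replacement), `dE_H/dt = max(0, (1-kappa) p_C - p_J)` before puberty and
#' `dE_R/dt = kappa_R max(0, (1-kappa) p_C - p_J)` after. Exactly one of the
#' maturity and reproduction derivatives is non-zero at any state.
#'
#' @param state an [organism_state()]
#' @param p_A assimilation flux (J d^-1), >= 0; zero for embryos
#' @inheritParams specific_growth_rate
#' @return named list of derivatives `dL`, `dE`, `dE_H`, `dE_R` plus the
#'   fluxes `r`, `p_C`, `p_J` used to compute them
#' @export
state_derivatives <- function(state, p_A, params, F_t = 1) {
  if (p_A < 0) stop("assimilation flux p_A must be non-negative")
  fl <- deb_fluxes(state, params, F_t)
  net <- max(0, (1 - params$kappa) * fl$p_C - fl$p_J)
  adult <- state$E_H >= params$EH_p
  list(dL = max(0, fl$r) / 3 * state$L,
       dE = p_A - fl$p_C,
       dE_H = if (adult) 0 else net,
       dE_R = if (adult) params$kappa_R * net else 0,
       r = fl$r, p_C = fl$p_C, p_J = fl$p_J)
}

#' Initial egg state
#'
#' Embryo initial condition: reserve `E(0) = U_E0 * p_am` (the energy cost
#' of one egg), zero maturity and reproduction buffer, and a small seed
#' structural length (the growth equation cannot start from `L = 0`;
#' results are insensitive to the seed below 1e-3 cm).
#'
#' @param params a [deb_params()] object
#' @param L_seed seed structural length (cm)
#' @return an [organism_state()] at stage `"embryo"`
#' @examples
#' initial_egg_state(deb_params())$E   # 0.078 * 1673.9 = 130.56 J
#' @export
initial_egg_state <- function(params, L_seed = 1e-4) {
  organism_state(L = L_seed, E = params$U_E0 * params$p_am,
                 E_H = 0, E_R = 0, params = params)
}

#' Scaled reserve density
#'
#' `e = E v / (p_am L^3)`: reserve per unit structure relative to the
#' maximum reserve density `p_am / v`. Equals the scaled functional response
#' `f` at feeding equilibrium; temperature-invariant (both `p_am` and `v`
#' carry the same correction).
#'
#' @inheritParams specific_growth_rate
#' @return dimensionless scaled reserve density
#' @export
scaled_reserve_density <- function(E, L, params) {
  E * params$v / (params$p_am * L^3)
}
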