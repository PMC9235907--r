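#' DEB parameter set for *Aporrectodea caliginosa*
#'
#' Construct and validate the full parameter vector of the movement-extended
#' dynamic energy budget model. Called with no arguments it returns the
#' reference parameterization for *A. caliginosa* at a reference temperature
#' of 293.10 K; any subset of parameters can be overridden by name.
#'
#' @param ... named parameter overrides, e.g. `deb_params(kappa = 0.45)`.
#'   Unknown names are an error.
#'
#' @return An object of class `deb_params`: a named list of 26 numeric
#'   parameters.
#'
#' @details Parameters (units in parentheses):
#' \describe{
#'   \item{p_am}{surface-area-specific maximum assimilation flux (J d^-1 cm^-2)}
#'   \item{v}{energy conductance (cm d^-1)}
#'   \item{kappa}{allocation fraction to soma (-)}
#'   \item{p_M}{volume-specific somatic maintenance (J d^-1 cm^-3)}
#'   \item{E_G}{specific cost for structure (J cm^-3)}
#'   \item{k_J}{maturity maintenance rate coefficient (d^-1)}
#'   \item{EH_b, EH_p}{maturity thresholds at birth and puberty (J)}
#'   \item{kappa_R}{reproduction efficiency (-)}
#'   \item{U_E0}{cost for an egg (cm^2 d); initial reserve is `U_E0 * p_am` J}
#'   \item{t_0}{pre-development delay of cocoons (d)}
#'   \item{F_m}{maximum specific searching rate (g d^-1 cm^-2)}
#'   \item{kappa_X}{digestion efficiency of food to reserve (-)}
#'   \item{mu_OM}{organic matter-energy coupler (J g^-1 %^-1)}
#'   \item{m_0}{moisture threshold for movement (\%)}
#'   \item{k_b}{moisture-dependent specific movement rate (cm d^-1 %^-1 cm^-2)}
#'   \item{b_max}{maximum moisture-dependent specific movement rate (cm d^-1 %^-1 cm^-2)}
#'   \item{b_w}{distribution width for diapause (%^-1)}
#'   \item{T_A, T_AH}{Arrhenius temperatures for the main branch and the
#'     upper-boundary correction (K)}
#'   \item{T_H}{upper temperature boundary (K)}
#'   \item{T_ref}{reference temperature (K)}
#'   \item{delta_M}{shape coefficient (-)}
#'   \item{delta_V}{specific density of structure (g cm^-3)}
#'   \item{w, w_V}{contributions of reserve and of water replacement to fresh
#'     weight (g cm^-3)}
#' }
#'
#' @examples
#' p <- deb_params()
#' p$kappa * p$p_am / p$p_M        # ultimate structural length (cm)
#' deb_params(kappa = 0.45)$kappa
#' @export
deb_params <- function(...) {
  p <- deb_param_defaults()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("parameter overrides must be named")
    bad <- setdiff(names(over), names(p))
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- lapply(over, as.numeric)
  }
  validate_deb_params(structure(p, class = "deb_params"))
}

# Reference values (reference temperature 293.10 K); t_0 is the cocoon
# pre-development delay.
deb_param_defaults <- function() {
  list(
    # core energetics
    p_am   = 1673.9,
    v      = 0.017,
    kappa  = 0.40,
    p_M    = 1560,
    E_G    = 4194,
    k_J    = 0.0028,
    EH_b   = 16.79,
    EH_p   = 1131,
    kappa_R = 0.48,
    U_E0   = 0.078,
    t_0    = 40.2,
    # movement / feeding
    F_m    = 85.78,
    kappa_X = 0.26,
    mu_OM  = 186.20,
    m_0    = 8.69,
    k_b    = 6.205,
    b_max  = 87.98,
    b_w    = 0.78,
    # temperature correction
    T_A    = 7976,
    T_AH   = 28750,
    T_H    = 293.20,
    T_ref  = 293.10,
    # conversions
    delta_M = 0.065,
    delta_V = 0.27,
    w      = 27.24,
    w_V    = 6.72
  )
}

#' @export
print.deb_params <- function(x, ...) {
  cat("<deb_params> movement-extended DEB parameter set (", length(x),
      " parameters)\n", sep = "")
  df <- data.frame(value = unlist(x))
  print(df, ...)
  invisible(x)
}

deb_param_units <- function() {
  c(p_am = "J/d.cm^2", v = "cm/d", kappa = "-", p_M = "J/d.cm^3",
    E_G = "J/cm^3", k_J = "1/d", EH_b = "J", EH_p = "J", kappa_R = "-",
    U_E0 = "cm^2.d", t_0 = "d", F_m = "g/d.cm^2", kappa_X = "-",
    mu_OM = "J/g.%", m_0 = "%", k_b = "cm/d.%.cm^2", b_max = "cm/d.%.cm^2",
    b_w = "1/%", T_A = "K", T_AH = "K", T_H = "K", T_ref = "K",
    delta_M = "-", delta_V = "g/cm^3", w = "g/cm^3", w_V = "g/cm^3")
}

validate_deb_params <- function(p) {
  v <- unlist(p)
  if (any(!is.finite(v))) stop("non-finite parameter value(s)")
  if (any(v <= 0))
    stop("all parameters must be strictly positive; offending: ",
         paste(names(v)[v <= 0], collapse = ", "))
  for (k in c("kappa", "kappa_R", "kappa_X"))
    if (p[[k]] > 1)
      stop(k, " must lie in (0, 1], got ", p[[k]])
  if (p$EH_b >= p$EH_p)
    stop("maturity at birth (EH_b) must be below maturity at puberty (EH_p)")
  if (p$T_H < p$T_ref)
    stop("upper temperature boundary T_H must not be below T_ref")
  p
}

# parameters optimized on the logit scale (fractions); everything else log
logit_params <- function() c("kappa", "kappa_R", "kappa_X")

transform_params <- function(p, free) {
  x <- unlist(p[free])
  lg <- free %in% logit_params()
  x[lg] <- stats::qlogis(x[lg])
  x[!lg] <- log(x[!lg])
  x
}

untransform_params <- function(x, free, p) {
  lg <- free %in% logit_params()
  x[lg] <- stats::plogis(x[lg])
  x[!lg] <- exp(x[!lg])
  p[free] <- as.list(unname(x))
  validate_deb_params(p)
}
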