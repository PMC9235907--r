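# Reference parameter values used as independent literals in oracle
# arithmetic (kept separate from deb_params() so a constructor regression
# cannot silently propagate into expected values).
ref <- list(
  b_w = 0.78, EH_b = 16.79, EH_p = 1131, E_G = 4194, F_m = 85.78,
  k_J = 0.0028, m_0 = 8.69, b_max = 87.98, p_am = 1673.9, p_M = 1560,
  k_b = 6.205, T_A = 7976, T_AH = 28750, T_H = 293.20, T_ref = 293.10,
  U_E0 = 0.078, v = 0.017, w = 27.24, w_V = 6.72, delta_M = 0.065,
  delta_V = 0.27, kappa = 0.40, kappa_R = 0.48, kappa_X = 0.26,
  mu_OM = 186.20, t_0 = 40.2)

# trapezoid quadrature over a tabulated integrand
trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

# dense juvenile-to-adult reference trajectory reused across tests
default_env <- function(T_C = deb_params()$T_ref - 273.15)
  deb_environment(T_C = T_C, M = 20, OM = 4)
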