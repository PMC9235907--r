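test_that("egg-to-adult simulation orders events and respects the delay", {
  p <- deb_params()
  sc <- deb_scenario(default_env(), duration = 400, initial = "egg", f = 1)
  tr <- simulate_deb(sc, p)
  ev <- tr$events
  # at reference temperature F_t = 1, so the lag equals t_0 exactly
  expect_gt(ev$age_at_birth, p$t_0)
  expect_lt(ev$age_at_birth, p$t_0 + 100)
  expect_gt(ev$age_at_puberty, ev$age_at_birth)
  expect_equal(ev$time_since_birth_at_puberty,
               ev$age_at_puberty - ev$age_at_birth)
  st <- tr$states
  expect_true(all(diff(st$time) > 0))
  expect_true(all(st$E >= 0 & st$EH_J >= 0 & st$ER_J >= 0, na.rm = TRUE))
  expect_true(all(diff(st$eggs_cum) >= -1e-12))
  # stages change exactly at the detected events
  expect_identical(st$stage[st$time < ev$age_at_birth][1], "embryo")
  expect_identical(st$stage[which.max(st$time)], "adult")
})

test_that("structural length follows the closed-form von Bertalanffy curve", {
  p <- deb_params()
  L_0 <- 0.1
  dur <- 300
  sc <- deb_scenario(default_env(), duration = dur, initial = "juvenile",
                     L_0 = L_0, e_0 = 1, f = 1,
                     times = seq(0, dur, by = 2))
  tr <- simulate_deb(sc, p)
  L_inf <- p$kappa * p$p_am / p$p_M
  k_M <- p$p_M / p$E_G
  r_B <- 1 / (3 / k_M + 3 * L_inf / p$v)
  L_vb <- L_inf - (L_inf - L_0) * exp(-r_B * tr$states$time)
  expect_lt(max(abs(tr$states$L_cm - L_vb) / L_vb), 0.005)
  # monotone approach to the ultimate length
  expect_true(all(diff(tr$states$Lw_cm) > 0))
})

test_that("the simulated asymptote matches the analytic ultimate length", {
  p <- deb_params()
  sc <- deb_scenario(default_env(), duration = 800, initial = "juvenile",
                     L_0 = 0.1, e_0 = 1, f = 1)
  tr <- simulate_deb(sc, p)
  L_inf <- p$kappa * p$p_am / p$p_M
  expect_equal(tail(tr$states$L_cm, 1), L_inf, tolerance = 1e-3)
})

test_that("cumulative eggs match an independent quadrature of the buffer flux", {
  p <- deb_params()
  dur <- 14
  L_0 <- 0.3
  sc <- deb_scenario(default_env(), duration = dur, initial = "adult",
                     L_0 = L_0, e_0 = 1, f = 1,
                     times = seq(0, dur, by = 0.02))
  tr <- simulate_deb(sc, p)
  st <- tr$states
  r <- specific_growth_rate(st$E_J, st$L_cm, p)
  p_C <- mobilization_flux(st$E_J, st$L_cm, r, p)
  p_J <- maturity_maintenance(st$EH_J, p)
  flux <- p$kappa_R * pmax(0, (1 - p$kappa) * p_C - p_J) /
    (p$U_E0 * p$p_am)
  eggs_quad <- trapz(st$time, flux)
  expect_gt(tail(st$eggs_cum, 1), 0)
  expect_equal(tail(st$eggs_cum, 1), eggs_quad, tolerance = 1e-3)
})

test_that("energy is conserved along the trajectory to within 0.5%", {
  p <- deb_params()
  sc <- deb_scenario(default_env(), duration = 120, initial = "juvenile",
                     L_0 = 0.1, e_0 = 0.8, f = 0.9,
                     times = seq(0, 120, by = 0.05))
  tr <- simulate_deb(sc, p)
  st <- tr$states
  n <- nrow(st)
  p_A <- 0.9 * p$p_am * st$L_cm^2
  p_J <- maturity_maintenance(st$EH_J, p)
  maint <- p$p_M * st$L_cm^3
  lhs <- (st$E_J[n] - st$E_J[1]) +
    (st$EH_J[n] - st$EH_J[1]) +
    (st$ER_J[n] - st$ER_J[1]) / p$kappa_R +
    p$E_G * (st$L_cm[n]^3 - st$L_cm[1]^3) +
    trapz(st$time, maint + p_J)
  rhs <- trapz(st$time, p_A)
  expect_equal(lhs, rhs, tolerance = 0.005)
})

test_that("temperature rescales time exactly", {
  p <- deb_params()
  T_warm <- 25
  F_t <- temperature_correction(T_warm, p)
  dur <- 50
  times_w <- seq(0, dur, length.out = 41)
  tr_w <- simulate_deb(
    deb_scenario(deb_environment(T_C = T_warm, M = 20, OM = 4),
                 duration = dur, initial = "juvenile", L_0 = 0.1,
                 f = 1, times = times_w), p)
  tr_r <- simulate_deb(
    deb_scenario(default_env(), duration = dur * F_t,
                 initial = "juvenile", L_0 = 0.1, f = 1,
                 times = times_w * F_t), p)
  expect_equal(tr_w$states$L_cm, tr_r$states$L_cm, tolerance = 1e-6)
  expect_equal(tr_w$states$EH_J, tr_r$states$EH_J, tolerance = 1e-6)
})

test_that("event times are stable under tighter integrator tolerances", {
  p <- deb_params()
  sc <- deb_scenario(default_env(), duration = 300, initial = "egg", f = 1)
  ev1 <- simulate_deb(sc, p, deb_control())$events
  ev2 <- simulate_deb(sc, p, deb_control(rtol = 5e-9, atol = 5e-11))$events
  expect_lt(abs(ev1$age_at_birth - ev2$age_at_birth) / ev2$age_at_birth,
            1e-3)
  expect_lt(abs(ev1$age_at_puberty - ev2$age_at_puberty) /
              ev2$age_at_puberty, 1e-3)
})

test_that("results are insensitive to the embryo seed length below 1e-3 cm", {
  p <- deb_params()
  sc <- deb_scenario(default_env(), duration = 200, initial = "egg")
  ev_ref <- simulate_deb(sc, p, deb_control(L_seed = 1e-4))$events
  for (seed_L in c(1e-5, 2e-4)) {
    ev <- simulate_deb(sc, p, deb_control(L_seed = seed_L))$events
    expect_lt(abs(ev$age_at_birth - ev_ref$age_at_birth) /
                ev_ref$age_at_birth, 1e-3)
  }
})

test_that("the cocoon delay is temperature-corrected when enabled", {
  p <- deb_params()
  env10 <- deb_environment(T_C = 10, M = 20, OM = 4)
  sc <- deb_scenario(env10, duration = 1500, initial = "egg")
  F_t <- temperature_correction(10, p)
  ev_corr <- simulate_deb(sc, p)$events
  ev_raw <- simulate_deb(sc, p,
                         deb_control(t0_temperature_corrected = FALSE))$events
  expect_equal(ev_corr$age_at_birth * F_t,
               simulate_deb(deb_scenario(default_env(), duration = 300,
                                         initial = "egg"), p)$events$age_at_birth,
               tolerance = 1e-5)
  expect_equal(ev_raw$age_at_birth - ev_corr$age_at_birth,
               p$t_0 - p$t_0 / F_t, tolerance = 1e-5)
})

test_that("feeding level can switch at puberty", {
  p <- deb_params()
  dur <- 250
  sc_hi <- deb_scenario(default_env(), duration = dur, initial = "juvenile",
                        L_0 = 0.1, f = 1.1, times = seq(0, dur, by = 1))
  sc_sw <- deb_scenario(default_env(), duration = dur, initial = "juvenile",
                        L_0 = 0.1, f = 1.1, f_adult = 0.87,
                        times = seq(0, dur, by = 1))
  tr_hi <- simulate_deb(sc_hi, p)
  tr_sw <- simulate_deb(sc_sw, p)
  tp <- tr_sw$events$age_at_puberty
  expect_false(is.na(tp))
  pre <- tr_sw$states$time <= tp
  expect_equal(tr_sw$states$Ww_g[pre], tr_hi$states$Ww_g[pre],
               tolerance = 1e-8)
  expect_lt(tail(tr_sw$states$Ww_g, 1), tail(tr_hi$states$Ww_g, 1))
})

test_that("weight and length conversions follow the printed forms", {
  p <- deb_params()
  expect_equal(physical_length(0.0975, p), 1.5)
  expect_equal(physical_length(0.43550, p), 6.7)
  expect_identical(physical_length(0, p), 0)
  expect_equal(dry_weight(0.26, 1, p), 0.26^3 * 0.27 * 28.24)
  expect_identical(dry_weight(0, 1, p), 0)
  expect_equal(dry_weight(0.2, 0, p), 0.2^3 * 0.27)
  expect_equal(fresh_weight(0.42921, 1, p), 0.42921^3 * 28.24)
  expect_equal(fresh_weight(0.2, 0, p), 0.2^3 * (1 + p$w_V))
  # water replacement damps weight change: slope in e is w - w_V per L^3
  L <- 0.3
  slope <- (fresh_weight(L, 0.9, p) - fresh_weight(L, 0.8, p)) / 0.1
  expect_equal(slope, L^3 * (p$w - p$w_V), tolerance = 1e-10)
  expect_gt(slope, 0)
  # gut content is additive
  expect_equal(fresh_weight(0.3, 1, p, gut_content = 0.3) -
                 fresh_weight(0.3, 1, p), 0.3)
})

test_that("egg conversion is linear with the printed cost", {
  p <- deb_params()
  expect_identical(eggs_from_buffer(0, p), 0)
  expect_equal(eggs_from_buffer(130.5642, p), 1, tolerance = 1e-10)
  expect_equal(eggs_from_buffer(261.1284, p), 2, tolerance = 1e-10)
  expect_identical(eggs_from_buffer(200, p, integer = TRUE),
                   floor(eggs_from_buffer(200, p)))
  expect_error(eggs_from_buffer(-1, p), "non-negative")
})

test_that("population summaries average trajectories and weight movers", {
  p <- deb_params()
  sc <- deb_scenario(default_env(), duration = 20, initial = "juvenile",
                     L_0 = 0.1, f = 1, times = seq(0, 20, by = 5))
  tr <- simulate_deb(sc, p)
  s1 <- population_summary(list(tr))
  expect_equal(s1$Ww_g_mean, tr$states$Ww_g)
  expect_true(all(s1$Ww_g_sd == 0))
  s2 <- population_summary(list(tr, tr))
  expect_true(all(s2$L_cm_sd == 0))
  sD <- population_summary(list(tr, tr), D = 1)
  expect_true(all(sD$burrow_cm_per_d_mean == 0))
  expect_error(population_summary(list()), "empty")
})
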