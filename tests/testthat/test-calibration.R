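test_that("mean relative error follows its definition", {
  expect_identical(as.numeric(mean_relative_error(1, 1)), 0)
  expect_equal(as.numeric(mean_relative_error(1.1, 1.0)), 0.1)
  # datasets average unweighted: per-dataset errors 0.2 and 0 give 0.1
  ds_p <- list(list(pred = c(1.2, 1.2), obs = c(1, 1), weights = NULL),
               list(pred = 5, obs = 5, weights = NULL))
  expect_equal(as.numeric(mean_relative_error(ds_p, ds_p)), 0.1)
  expect_error(mean_relative_error(1, 0), "zero observation")
  # within-dataset weighting
  expect_equal(as.numeric(mean_relative_error(c(1.2, 1), c(1, 1),
                                              weights = c(1, 3))), 0.05)
})

test_that("symmetric mean squared error is bounded and matches arithmetic", {
  expect_identical(as.numeric(symmetric_mean_squared_error(2, 2)), 0)
  expect_equal(as.numeric(symmetric_mean_squared_error(0, 1)), 1)
  expect_equal(as.numeric(symmetric_mean_squared_error(1, 2)), 1 / 5)
  expect_error(symmetric_mean_squared_error(0, 0), "all-zero")
  set.seed(5)
  for (i in 1:10) {
    o <- runif(6, 0.1, 10); pr <- runif(6, 0.1, 10)
    v <- as.numeric(symmetric_mean_squared_error(pr, o))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("relative measures are invariant under unit rescaling", {
  o <- c(2, 3, 4); pr <- c(2.2, 2.7, 4.4)
  for (c_scale in c(1e-3, 1e3)) {
    expect_equal(as.numeric(mean_relative_error(pr * c_scale, o * c_scale)),
                 as.numeric(mean_relative_error(pr, o)))
    expect_equal(as.numeric(symmetric_mean_squared_error(pr * c_scale,
                                                         o * c_scale)),
                 as.numeric(symmetric_mean_squared_error(pr, o)))
  }
})

test_that("the calibration loss is the unnormalized symmetric kernel", {
  o <- c(2, 3, 4); pr <- c(2.2, 2.7, 4.4)
  expect_identical(deb_loss(o, o), 0)
  w <- rep(1 / 3, 3)
  expect_equal(deb_loss(pr, o, weights = w),
               sum(w) * as.numeric(symmetric_mean_squared_error(pr, o,
                                                                weights = w)))
  expect_equal(deb_loss(pr, o, weights = 2 * w),
               2 * deb_loss(pr, o, weights = w))
})

test_that("zero-variate predictions match the closed forms", {
  p <- deb_params()
  zv <- predict_zero_variate(p)
  L_inf <- ref$kappa * ref$p_am / ref$p_M
  expect_equal(unname(zv["ultimate_length"]), L_inf / ref$delta_M,
               tolerance = 1e-10)
  expect_equal(unname(zv["ultimate_fresh_weight"]), L_inf^3 * (1 + ref$w),
               tolerance = 1e-10)
  # doubling somatic maintenance halves the ultimate length
  zv2 <- predict_zero_variate(deb_params(p_M = 2 * ref$p_M))
  expect_equal(unname(zv2["ultimate_length"]),
               unname(zv["ultimate_length"]) / 2, tolerance = 1e-10)
  # weights derive from the event-state structural lengths
  d <- attr(zv, "details")
  expect_equal(unname(zv["fresh_weight_at_puberty"]),
               d$L_p^3 * (1 + ref$w), tolerance = 1e-10)
  expect_equal(unname(zv["length_at_birth"]), d$L_b / ref$delta_M)
  # duration scales with the reporting temperature
  zv15 <- predict_zero_variate(p, temp_C_tp = 15)
  zv20 <- predict_zero_variate(p, temp_C_tp = ref$T_ref - 273.15)
  expect_equal(unname(zv15["time_since_birth_at_puberty"]) *
                 temperature_correction(15, p),
               unname(zv20["time_since_birth_at_puberty"]),
               tolerance = 1e-10)
  expect_error(predict_zero_variate(p, max_days = 5), "not reached")
})

test_that("an empty free set evaluates without optimizing", {
  p <- deb_params()
  obs <- observation_set(datasets = list(
    deb_dataset("diapause", "diapause_fraction", x = c(9, 10, 12),
                obs = diapause_fraction(c(9, 10, 12), p))))
  f <- fit_deb(obs, p, free = character())
  expect_identical(f$evaluations, 0)
  expect_identical(unlist(f$params), unlist(p))
  expect_equal(f$MRE, 0)
  expect_equal(f$SMSE, 0)
  expect_equal(f$loss, 0)
})

test_that("noiseless data are recovered to 1e-4 from an off-truth start", {
  p_true <- deb_params()
  syn_b <- generate_experiment(experiment_design("burrow_moisture", cv = 0),
                               p_true)
  syn_d <- generate_experiment(experiment_design("diapause_moisture", cv = 0),
                               p_true)
  obs <- observation_set(datasets = c(syn_b$observation_set$datasets,
                                      syn_d$observation_set$datasets))
  f <- fit_deb(obs, deb_params(m_0 = 8.0, b_w = 0.9),
               free = c("m_0", "b_w"))
  expect_lt(abs(f$params$m_0 - p_true$m_0) / p_true$m_0, 1e-4)
  expect_lt(abs(f$params$b_w - p_true$b_w) / p_true$b_w, 1e-4)
  expect_lt(f$loss, 1e-10)
})

test_that("the optimizer is stationary at the generating parameters", {
  p_true <- deb_params()
  syn <- generate_experiment(experiment_design("burrow_moisture", cv = 0),
                             p_true)
  f <- fit_deb(syn$observation_set, p_true, free = c("m_0", "k_b"))
  expect_lt(f$loss, 1e-12)
  expect_lt(abs(f$params$m_0 - p_true$m_0) / p_true$m_0, 1e-6)
  expect_lt(abs(f$params$k_b - p_true$k_b) / p_true$k_b, 1e-6)
})

test_that("jointly fitting k_b and b_max from moisture-response data warns", {
  p <- deb_params()
  M <- c(10, 12, 14, 16, 18, 20)
  obs <- observation_set(datasets = list(
    deb_dataset("fm", "moisture_response", M,
                moisture_functional_response(M, p))))
  expect_warning(fit_deb(obs, p, free = c("k_b", "b_max"),
                         config = fit_control(maxit = 2000,
                                              restart = FALSE)),
                 "under-determined")
  # the same pair is identifiable from absolute burrow rates
  obs2 <- observation_set(datasets = list(
    deb_dataset("B", "burrow_rate", M, burrow_rate(M, 0.25, p),
                scenario = list(L = 0.25, T_C = 20)),
    deb_dataset("fm", "moisture_response", M,
                moisture_functional_response(M, p))))
  f2 <- suppressWarnings(fit_deb(obs2, p, free = c("k_b", "b_max"),
                                 config = fit_control(maxit = 50,
                                                      restart = FALSE)))
  expect_false(f2$collinear)
})

test_that("zero-variate entries enter the fit as individual datasets", {
  p <- deb_params()
  zv_true <- predict_zero_variate(p)
  zv <- data.frame(name = c("ultimate_length", "ultimate_fresh_weight"),
                   value = c(zv_true[["ultimate_length"]] * 1.1,
                             zv_true[["ultimate_fresh_weight"]]))
  obs <- observation_set(zero_variate = zv)
  f <- fit_deb(obs, p, free = character())
  expect_equal(unname(f$per_dataset_re["ultimate_length"]), 1 - 1 / 1.1,
               tolerance = 1e-6)
  expect_equal(f$MRE, (1 - 1 / 1.1) / 2, tolerance = 1e-6)
  expect_error(observation_set(zero_variate = data.frame(name = "nope",
                                                         value = 1)),
               "unknown zero-variate")
})

test_that("fit errors name unknown free parameters", {
  obs <- observation_set(datasets = list(
    deb_dataset("d", "diapause_fraction", 10, 0.4)))
  expect_error(fit_deb(obs, deb_params(), free = "zeta"), "zeta")
})
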