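test_that("mean squared error against observations has its closed forms", {
  sim <- simulate_remodeling(menopause_schedule("combined"),
                             ensemble = tiny_ensemble(), t_end = 6)
  tt <- seq(-3.5, 5.5, by = 0.5)
  pred <- approx(sim$time, sim$femur$bmd_rel, xout = tt)$y
  # observations sampled from the simulation itself
  expect_equal(bmd_mse(sim, bmd_observations(tt, pred)), 0)
  # constant offset
  expect_equal(bmd_mse(sim, bmd_observations(tt, pred + 0.02)), 4e-4)
  # explicit residuals
  obs2 <- bmd_observations(c(0, 1), approx(sim$time, sim$femur$bmd_rel,
                                           xout = c(0, 1))$y + c(0.01, -0.03))
  expect_equal(bmd_mse(sim, obs2), (0.01^2 + 0.03^2) / 2)
  # out-of-span observations are refused
  expect_error(bmd_mse(sim, bmd_observations(c(0, 40), c(1, 0.9))), "span")
})

test_that("observation series validate and round-trip through CSV", {
  expect_error(bmd_observations(c(0, 0), c(1, 1)))
  expect_error(bmd_observations(c(0, 1), c(1, -1)))
  obs <- bmd_observations(c(-4, 0, 4), c(1, 0.98, 0.94), sd = rep(0.005, 3))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back$t_years, obs$t_years)
  expect_equal(back$bmd_rel, obs$bmd_rel)
  expect_equal(back$sd, obs$sd)
})

test_that("noiseless self-generated data is recovered nearly exactly", {
  obs <- generate_observations(menopause_schedule("fbio_only"), noise_sd = 0)
  fit <- fit_kappa(obs, "fbio_only")
  expect_lt(abs(coef(fit)[["kappa_perm_fbio"]] / 1.489 - 1), 0.02)
  expect_lt(fit$mse, 1e-8)
  # optimum is at least as good as every grid point the search visited
  expect_lte(fit$mse, min(fit$trace$mse) + 1e-15)
  expect_s3_class(fit$schedule, "menopause_schedule")
})

test_that("a flat series fits at the no-change boundary", {
  obs <- bmd_observations(seq(-4, 15, by = 1), rep(1, 20))
  fit <- fit_kappa(obs, "fbb_only",
                   control = list(grid_n = 5, refine_levels = 0))
  expect_equal(coef(fit)[["kappa_perm_fbb"]], 1, tolerance = 1e-4)
  expect_lt(fit$mse, 1e-6)
})

test_that("the fit is invariant to rescaling the observation series", {
  obs <- generate_observations(menopause_schedule("fbb_only"),
                               times = seq(-4, 10, by = 1),
                               noise_sd = 0.004, seed = 3)
  obs_scaled <- bmd_observations(obs$t_years, obs$bmd_rel * 1.05)
  ctrl <- list(grid_n = 5, refine_levels = 1)
  f1 <- fit_kappa(obs, "fbb_only", control = ctrl)
  f2 <- fit_kappa(obs_scaled, "fbb_only", control = ctrl)
  # identical up to the optimizer's own termination precision
  expect_equal(coef(f1), coef(f2), tolerance = 1e-3)
  expect_equal(f2$scale / f1$scale, 1.05, tolerance = 1e-4)
})

test_that("fit methods expose coefficients, predictions and residuals", {
  obs <- generate_observations(menopause_schedule("fbb_only"),
                               times = seq(-4, 8, by = 1),
                               noise_sd = 0.005, seed = 5)
  fit <- fit_kappa(obs, "fbb_only", control = list(grid_n = 3, refine_levels = 0,
                                                   polish_maxit = 40))
  expect_named(coef(fit), c("kappa_perm_fbb", "slope_fbb"))
  expect_equal(length(predict(fit)), nrow(obs))
  expect_equal(residuals(fit), obs$bmd_rel - fit$fitted)
  expect_lt(sqrt(mean(residuals(fit)^2)), 0.02)
  expect_output(print(fit), "fbb_only")
  expect_output(print(summary(fit)), "rmse")
  pred5 <- predict(fit, t_years = c(0, 5))
  expect_equal(length(pred5), 2)
  expect_gt(pred5[1], pred5[2])  # declining trajectory
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "bmd_obs")
})
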