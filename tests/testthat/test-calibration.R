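test_that("rmse follows its definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt((9 + 16) / 2))
  expect_error(rmse(1:3, 1:2), "equal length")
  expect_error(rmse(numeric(0), numeric(0)), "equal length")
})

test_that("noiseless synthetic observations are recovered exactly", {
  # inverse-crime check: data generated by the forward model at a known
  # absorption fraction must be fit back to it
  sp <- synth_spec(seed = 3L, xi_abs_true = 0.05, noise_sd = 0)
  synth <- synth_temperature_observations(sp)
  fit <- fit_absorption_fraction(synth$observations, xi_density = 0.17)
  expect_equal(fit$xi_abs, 0.05, tolerance = 1e-5)
  expect_true(fit$converged)
  expect_lt(fit$rmse, 1e-4)
})

test_that("degenerate all-zero observations pin the fit to its lower bound", {
  obs <- data.frame(power = c(0.0695, 0.178), t_obs = c(60, 120),
                    delta_T_mean = c(0, 0), delta_T_se = c(0.3, 0.3))
  fit <- fit_absorption_fraction(obs)
  expect_false(fit$converged)
  expect_lt(fit$xi_abs, 1e-3)
})

test_that("predicted increments grow strictly with the absorption fraction", {
  p <- default_params()
  g <- coarse_grid()
  prot <- nir_protocol_calibration()
  lo <- solve_temperature(p, source_fractions(0.17, 0.1), prot, grid = g,
                          times = c(60, 120, 180, 240))
  hi <- solve_temperature(p, source_fractions(0.17, 0.2), prot, grid = g,
                          times = c(60, 120, 180, 240))
  expect_true(all(hi$delta_T[-1L, 1L] > lo$delta_T[-1L, 1L]))
})

test_that("repeated fits on identical inputs are bit-identical", {
  obs <- reference_observations()
  f1 <- fit_absorption_fraction(obs, grid = coarse_grid())
  f2 <- fit_absorption_fraction(obs, grid = coarse_grid())
  expect_identical(f1$xi_abs, f2$xi_abs)
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$rmse, f2$rmse)
})

test_that("fit accessors expose the standard modelling interface", {
  fit <- fit_absorption_fraction(reference_observations(),
                                 grid = coarse_grid(97L))
  expect_named(coef(fit), "xi_abs")
  expect_length(fitted(fit), 4L)
  expect_equal(residuals(fit),
               reference_observations()$delta_T_mean - fitted(fit))
  pr <- predict(fit, times = c(60, 240))
  expect_equal(pr$delta_T, fit$predictions[c(1L, 4L)], tolerance = 1e-6)
  s <- summary(fit)
  expect_s3_class(s, "summary.absorption_fit")
  expect_equal(s$rmse, fit$rmse)
  sims <- simulate(fit, nsim = 2, seed = 11, noise_sd = 0.3)
  expect_length(sims, 2L)
  expect_false(identical(sims[[1L]]$delta_T_mean, sims[[2L]]$delta_T_mean))
  sims2 <- simulate(fit, nsim = 2, seed = 11, noise_sd = 0.3)
  expect_identical(sims, sims2)
})

test_that("weighting by reciprocal variance shifts the fit toward precise points", {
  obs <- reference_observations()
  fu <- fit_absorption_fraction(obs, grid = coarse_grid(97L))
  fw <- fit_absorption_fraction(obs, grid = coarse_grid(97L), weighted = TRUE)
  # the most precise observation (step 1) lies above the unweighted fit,
  # so weighting must pull xi_abs upward
  expect_gt(fw$xi_abs, fu$xi_abs)
})

test_that("observations outside the integrated window are rejected", {
  obs <- reference_observations()
  obs$t_obs[4L] <- 300
  expect_error(fit_absorption_fraction(obs), "integrated window")
  expect_error(fit_absorption_fraction(data.frame()), "columns")
  bad <- reference_observations(); bad$delta_T_se[1L] <- 0
  expect_error(fit_absorption_fraction(bad), "positive")
})

test_that("the transmittance bound on the absorption fraction is strict", {
  chk <- check_absorption_bound(0.17, 0.75)
  expect_true(chk$pass)
  expect_equal(chk$margin, 0.08)
  expect_false(check_absorption_bound(0.25, 0.75)$pass)  # boundary fails
  # any xi_abs above 1 - transmittance fails; below passes
  for (x in c(0.05, 0.2, 0.5, 0.9)) {
    eps <- 0.01
    expect_false(check_absorption_bound(x, 1 - x + eps)$pass)
    expect_true(check_absorption_bound(x, max(1 - x - eps, 1e-3))$pass)
  }
  expect_error(check_absorption_bound(0.2, 1), "0, 1")
})

test_that("observation CSV round-trips through the published column layout", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  obs <- reference_observations()
  write_observations(obs, path)
  expect_equal(read_observations(path), obs)
  header <- names(utils::read.csv(path))
  expect_equal(header, c("power_mW", "t_s", "dT_K", "se_K"))
})
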