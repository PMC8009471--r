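test_that("all generators are bit-identical under a fixed seed", {
  sp <- synth_spec(seed = 13L, image_size = 96L, axis_ratios = c(0.5, 1))
  a <- synth_temperature_observations(sp)
  b <- synth_temperature_observations(sp)
  expect_identical(a, b)
  expect_identical(synth_particle_image(sp), synth_particle_image(sp))
  expect_identical(synth_ellipse_masks(sp), synth_ellipse_masks(sp))
  f1 <- synth_fluorescence_trace(sp)
  f2 <- synth_fluorescence_trace(sp)
  expect_identical(f1, f2)
  # a different seed changes the noise realization
  c <- synth_temperature_observations(synth_spec(seed = 14L))
  expect_false(identical(a$observations$delta_T_mean,
                         c$observations$delta_T_mean))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(synth_temperature_observations(synth_spec(seed = 2L)))
  expect_identical(.Random.seed, before)
})

test_that("noiseless observations equal the forward-model predictions", {
  sp <- synth_spec(seed = 1L, noise_sd = 0)
  out <- synth_temperature_observations(sp)
  fld <- solve_temperature(sp$params,
                           source_fractions(sp$xi_density, sp$xi_abs_true),
                           sp$protocol, times = out$observations$t_obs,
                           rtol = 1e-8, atol = 1e-11)
  tr <- center_trace(fld)
  expect_equal(out$observations$delta_T_mean,
               tr$delta_T[match(out$observations$t_obs, tr$time)],
               tolerance = 1e-6)
  expect_identical(out$trace$delta_T_true, out$trace$delta_T_noisy)
  expect_true(all(out$observations$delta_T_se > 0))
})

test_that("noisy observations carry the injected noise scale", {
  sp <- synth_spec(seed = 8L, noise_sd = 0.3)
  out <- synth_temperature_observations(sp)
  resid <- out$trace$delta_T_noisy - out$trace$delta_T_true
  expect_equal(stats::sd(resid), 0.3, tolerance = 0.5)
  expect_equal(out$observations$t_obs, c(60, 120, 180, 240))
  expect_equal(out$observations$power, c(69.5, 178, 286.5, 395) * 1e-3)
})

test_that("particle images hit the requested coverage exactly", {
  sp <- synth_spec(seed = 4L, coverage_true = 0.17, image_size = 192L)
  img <- synth_particle_image(sp)
  expect_equal(img$coverage, round(0.17 * 192^2) / 192^2)
  expect_equal(occupancy_fraction(img, method = "fixed", threshold = 0.5),
               img$coverage)
  expect_equal(sum(img$mask) / length(img$mask), img$coverage)
  # recovered fraction is invariant to rotating the image
  rot <- t(img$pixels)[ncol(img$pixels):1, ]
  expect_equal(occupancy_fraction(rot, method = "fixed", threshold = 0.5),
               img$coverage)
  blank <- synth_particle_image(synth_spec(seed = 4L, coverage_true = 0,
                                           image_size = 64L))
  expect_equal(blank$coverage, 0)
  expect_error(synth_particle_image(synth_spec(coverage_true = 0.5)),
               "packing limit")
})

test_that("fluorescence traces round-trip through the thermometry module", {
  sp <- synth_spec(seed = 6L, noise_sd = 0, protocol = nir_protocol_full())
  out <- synth_fluorescence_trace(sp)
  rec <- trace_to_delta_T(out$trace)
  expect_equal(rec$delta_T, out$delta_T_true, tolerance = 1e-9)
  # laser-off protocol keeps F/F0 identically one
  quiet <- synth_spec(seed = 6L, noise_sd = 0,
                      protocol = power_protocol(0, 120, 0))
  expect_true(all(synth_fluorescence_trace(quiet)$trace$fluorescence == 1))
  # with noise, the recovered temperature residual matches the injected scale
  spn <- synth_spec(seed = 16L, noise_sd = 0.3, protocol = nir_protocol_full())
  noisy <- synth_fluorescence_trace(spn)
  resid <- trace_to_delta_T(noisy$trace)$delta_T - noisy$delta_T_true
  expect_equal(stats::sd(resid), 0.3, tolerance = 0.5)
})

test_that("ellipse masks encode their designed axis ratios and classes", {
  sp <- synth_spec(seed = 10L, image_size = 256L,
                   axis_ratios = c(0.2, 0.5, 0.9))
  em <- synth_ellipse_masks(sp)
  expect_equal(sort(unique(as.vector(em$mask[em$mask > 0]))), 1:3)
  rho <- roundness(region_shapes(em$mask))
  expect_equal(rho, c(0.2, 0.5, 0.9), tolerance = 0.02)
  # one designed ratio per morphology class, recovered exactly
  s <- summarize_roundness(rho)
  expect_equal(unname(s$class_fractions), c(1, 1, 1) / 3)
  one <- synth_ellipse_masks(synth_spec(seed = 10L, image_size = 128L,
                                        axis_ratios = 1))
  expect_equal(roundness(region_shapes(one$mask)), 1, tolerance = 0.02)
})
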