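test_that("grid construction pins a node on the spot edge", {
  p <- default_params()
  g <- radial_grid(p)
  expect_equal(g$n_nodes, 241L)
  expect_identical(g$radii[g$spot_index], p$spot_radius)
  expect_equal(g$radii[1L], 0)
  expect_equal(g$radii[g$n_nodes], p$domain_radius)
  g2 <- coarse_grid(49L)
  expect_identical(g2$radii[g2$spot_index], p$spot_radius)
  expect_error(radial_grid(p, 50L), "spot edge")
})

test_that("zero power yields an identically zero field", {
  fld <- solve_temperature(default_params(), source_fractions(0.17, 0.17),
                           constant_protocol(power = 0, t_end = 30),
                           grid = coarse_grid(), times = c(0, 10, 30))
  expect_true(all(fld$delta_T == 0))
})

test_that("the field starts at rest and stays finite", {
  fld <- solve_temperature(default_params(), source_fractions(0.17, 0.17),
                           constant_protocol(), grid = coarse_grid(),
                           times = c(0, 5, 60))
  expect_true(all(fld$delta_T[1L, ] == 0))
  expect_true(all(is.finite(fld$delta_T)))
  expect_gt(max(fld$delta_T), 0)
})

test_that("the solution is linear in the source fraction and in power", {
  p <- default_params()
  g <- coarse_grid()
  prot <- constant_protocol(t_end = 30)
  base <- solve_temperature(p, source_fractions(0.17, 0.1), prot, grid = g,
                            times = c(0, 10, 30))
  dbl <- solve_temperature(p, source_fractions(0.17, 0.2), prot, grid = g,
                           times = c(0, 10, 30))
  expect_equal(dbl$delta_T, 2 * base$delta_T, tolerance = 1e-6)
  prot2 <- constant_protocol(power = 2 * 69.5e-3, t_end = 30)
  dblP <- solve_temperature(p, source_fractions(0.17, 0.1), prot2, grid = g,
                            times = c(0, 10, 30))
  expect_equal(dblP$delta_T, 2 * base$delta_T, tolerance = 1e-6)
})

test_that("dimensional results are invariant to the reference-time choice", {
  p <- default_params()
  g <- coarse_grid()
  prot <- nir_protocol_calibration()
  tt <- c(0, 45, 60, 150, 240)
  a <- solve_temperature(p, source_fractions(0.17, 0.17), prot, grid = g,
                         times = tt, time_scale = "diffusive",
                         rtol = 1e-9, atol = 1e-12)
  b <- solve_temperature(p, source_fractions(0.17, 0.17), prot, grid = g,
                         times = tt, time_scale = "exchange",
                         rtol = 1e-9, atol = 1e-12)
  expect_equal(a$delta_T, b$delta_T, tolerance = 1e-6)
})

test_that("center trace is nondecreasing while power is nondecreasing", {
  fld <- solve_temperature(default_params(), source_fractions(0.17, 0.17),
                           nir_protocol_calibration(), grid = coarse_grid(),
                           times = seq(0, 240, by = 5),
                           rtol = 1e-8, atol = 1e-11)
  tr <- center_trace(fld)
  expect_equal(tr$time, seq(0, 240, by = 5))
  # nondecreasing up to integrator tolerance at the plateaus
  expect_true(all(diff(tr$delta_T) > -1e-6 * max(tr$delta_T)))
})

test_that("far-field boundary stays at ambient through the calibrated run", {
  fld <- solve_temperature(default_params(), source_fractions(0.17, 0.21),
                           nir_protocol_calibration(), grid = coarse_grid(97L),
                           times = seq(0, 240, by = 15))
  expect_lt(fld$far_field_max, 1e-3)
  expect_true(all(abs(fld$delta_T[, ncol(fld$delta_T)]) < 1e-3))
  # the node next to the boundary documents how unperturbed the far field is
  expect_lt(fld$edge_adjacent_max, 0.05 * max(fld$delta_T))
})

test_that("numerical steady state matches the Bessel closed form", {
  p <- default_params()
  fr <- source_fractions(0.17, 0.17)
  g <- radial_grid(p)  # default 241 nodes
  fld <- solve_temperature(p, fr, constant_protocol(), grid = g,
                           times = c(0, 60), rtol = 1e-9, atol = 1e-12)
  ex <- steady_state_closed_form(p, fr$xi, 69.5e-3, radii = g$radii)
  rel <- max(abs(fld$delta_T[2L, ] - ex$delta_T)) / max(ex$delta_T)
  expect_lt(rel, 5e-3)
})

test_that("suppressing conduction drives the center to the exchange balance", {
  # with k scaled down 1e4 the balance reduces to gamma dT = xi I_NIR
  p <- thermal_params(conductivity = 1.1e-4)
  fr <- source_fractions(0.17, 0.17)
  fld <- solve_temperature(p, fr, constant_protocol(t_end = 40),
                           grid = coarse_grid(97L, p), times = c(0, 40))
  plateau <- fr$xi * 69.5e-3 / (pi * p$spot_radius^2) / total_exchange(p)
  expect_equal(fld$delta_T[2L, 1L], plateau, tolerance = 1e-3)
})

test_that("long-format export reproduces the field", {
  fld <- solve_temperature(default_params(), source_fractions(0.17, 0.17),
                           constant_protocol(t_end = 10), grid = coarse_grid(),
                           times = c(0, 10))
  df <- as.data.frame(fld)
  expect_equal(nrow(df), 2L * 49L)
  expect_equal(df$delta_T[df$time == 10 & df$radius == 0],
               fld$delta_T[2L, 1L])
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_temperature_field(fld, path)
  expect_equal(utils::read.csv(path), df, tolerance = 1e-12)
})
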