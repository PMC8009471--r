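# Shared fixtures: the default substrate, coarse grids and short protocols
# keep individual tests fast while the acceptance tests use study-scale runs.

default_params <- function() thermal_params()

coarse_grid <- function(n = 49L, params = default_params()) {
  radial_grid(params, n)
}

constant_protocol <- function(power = 69.5e-3, t_end = 60) {
  power_protocol(0, t_end, power)
}

# measured spatial order of accuracy against the Bessel closed form over a
# refinement ladder (spacing halves between consecutive entries)
convergence_slope <- function(n_nodes, params = default_params(),
                              xi_abs = 0.17, xi_density = 0.17,
                              power = 69.5e-3) {
  fr <- source_fractions(xi_density, xi_abs)
  prot <- constant_protocol(power)
  errs <- vapply(n_nodes, function(n) {
    g <- radial_grid(params, n)
    fld <- solve_temperature(params, fr, prot, grid = g, times = c(0, 60),
                             rtol = 1e-10, atol = 1e-13)
    ex <- steady_state_closed_form(params, fr$xi, power, radii = g$radii)
    max(abs(fld$delta_T[2L, ] - ex$delta_T)) / max(abs(ex$delta_T))
  }, numeric(1))
  h <- 1 / (n_nodes - 1)
  unname(stats::coef(stats::lm(log2(errs) ~ log2(h)))[2L])
}
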