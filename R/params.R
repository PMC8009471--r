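#' Thermal and geometric parameters of the irradiated substrate
#'
#' Bundles the physical constants of the thin glass substrate and its
#' surroundings used by the heat-transfer model. The total surface exchange
#' coefficient is always derived as `exchange_water + exchange_air` and never
#' stored separately (the two faces of the substrate are not modelled
#' individually).
#'
#' Defaults describe a glass-bottom dish: a 0.2 mm thick glass disk of radius
#' 6 mm, irradiated over a central spot of radius 1.25 mm, exchanging heat with
#' water above (about 1e2 W m-2 K-1) and air below (about 1e1 W m-2 K-1), at a
#' room temperature of 298 K.
#'
#' @param exchange_water Heat-exchange coefficient with the liquid, W m-2 K-1.
#' @param exchange_air Heat-exchange coefficient with air, W m-2 K-1.
#' @param conductivity Thermal conductivity of glass, W m-1 K-1.
#' @param glass_density Density of glass, kg m-3.
#' @param specific_heat Specific heat of glass, J kg-1 K-1.
#' @param thickness Substrate thickness h, m.
#' @param spot_radius Radius of the irradiation spot, m.
#' @param domain_radius Outer radius of the substrate (far-field boundary), m.
#' @param ambient Ambient (room) temperature, K.
#'
#' @return An object of class `thermal_params`.
#' @seealso [total_exchange()], [power_protocol()], [solve_temperature()]
#' @export
#' @examples
#' p <- thermal_params()
#' total_exchange(p)
thermal_params <- function(exchange_water = 100,
                           exchange_air = 10,
                           conductivity = 1.1,
                           glass_density = 2500,
                           specific_heat = 840,
                           thickness = 2e-4,
                           spot_radius = 1.25e-3,
                           domain_radius = 6e-3,
                           ambient = 298) {
  p <- list(
    exchange_water = exchange_water,
    exchange_air = exchange_air,
    conductivity = conductivity,
    glass_density = glass_density,
    specific_heat = specific_heat,
    thickness = thickness,
    spot_radius = spot_radius,
    domain_radius = domain_radius,
    ambient = ambient
  )
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
  }
  if (p$spot_radius >= p$domain_radius)
    stop("'spot_radius' must be smaller than 'domain_radius'", call. = FALSE)
  structure(p, class = "thermal_params")
}

#' Total surface exchange coefficient
#'
#' @param params A [thermal_params()] object.
#' @return `exchange_water + exchange_air`, W m-2 K-1.
#' @export
total_exchange <- function(params) {
  stopifnot(inherits(params, "thermal_params"))
  params$exchange_water + params$exchange_air
}

#' @export
print.thermal_params <- function(x, ...) {
  cat("Thermal parameters of the irradiated substrate\n")
  cat(sprintf("  exchange (water + air): %g + %g = %g W m-2 K-1\n",
              x$exchange_water, x$exchange_air, total_exchange(x)))
  cat(sprintf("  conductivity: %g W m-1 K-1, density: %g kg m-3, specific heat: %g J kg-1 K-1\n",
              x$conductivity, x$glass_density, x$specific_heat))
  cat(sprintf("  thickness: %g mm, spot radius: %g mm, domain radius: %g mm\n",
              1e3 * x$thickness, 1e3 * x$spot_radius, 1e3 * x$domain_radius))
  cat(sprintf("  ambient temperature: %g K\n", x$ambient))
  invisible(x)
}

#' Timed step law of the NIR laser power
#'
#' Represents the laser power protocol P_NIR(t) as an ordered set of contiguous
#' constant-power segments. The first segment must start at t = 0, segments
#' must be contiguous and non-overlapping, and powers non-negative.
#'
#' @param t_start,t_end Segment start/end times, s.
#' @param power Segment powers, W.
#' @return An object of class `power_protocol` (a data frame with columns
#'   `t_start`, `t_end`, `power`).
#' @seealso [nir_protocol_full()], [nir_protocol_calibration()], [power_at()]
#' @export
#' @examples
#' power_protocol(c(0, 60), c(60, 120), c(0.0695, 0.178))
power_protocol <- function(t_start, t_end, power) {
  if (length(t_start) != length(t_end) || length(t_start) != length(power) ||
      length(t_start) < 1L)
    stop("'t_start', 't_end' and 'power' must have equal positive length",
         call. = FALSE)
  if (!all(is.finite(t_start)) || !all(is.finite(t_end)) || !all(is.finite(power)))
    stop("protocol entries must be finite", call. = FALSE)
  o <- order(t_start)
  t_start <- t_start[o]; t_end <- t_end[o]; power <- power[o]
  if (t_start[1L] != 0)
    stop("the first segment must start at t = 0", call. = FALSE)
  if (any(t_end <= t_start))
    stop("each segment must satisfy t_end > t_start", call. = FALSE)
  if (length(t_start) > 1L &&
      any(abs(t_start[-1L] - t_end[-length(t_end)]) > 1e-9))
    stop("segments must be contiguous and non-overlapping", call. = FALSE)
  if (any(power < 0))
    stop("powers must be non-negative", call. = FALSE)
  structure(
    data.frame(t_start = t_start, t_end = t_end, power = power),
    class = c("power_protocol", "data.frame")
  )
}

#' @export
print.power_protocol <- function(x, ...) {
  cat(sprintf("NIR power protocol: %d segment(s), span [0, %g] s\n",
              nrow(x), protocol_span(x)))
  df <- data.frame(t_start_s = x$t_start, t_end_s = x$t_end,
                   power_mW = 1e3 * x$power)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' End time of a power protocol
#'
#' @param protocol A [power_protocol()] object.
#' @return Last segment end time, s.
#' @export
protocol_span <- function(protocol) {
  stopifnot(inherits(protocol, "power_protocol"))
  max(protocol$t_end)
}

#' Laser power at given times
#'
#' Piecewise-constant evaluation of the step law. A time on a segment boundary
#' belongs to the later segment, except the final end time which belongs to the
#' last segment.
#'
#' @param protocol A [power_protocol()] object.
#' @param t Times, s (vectorised).
#' @return Power, W.
#' @export
power_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "power_protocol"))
  span <- protocol_span(protocol)
  if (any(t < -1e-9 | t > span + 1e-9))
    stop("time outside the protocol span [0, ", span, "] s", call. = FALSE)
  idx <- findInterval(pmin(pmax(t, 0), span), protocol$t_start,
                      rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  protocol$power[idx]
}

#' The full experimental laser step law
#'
#' The complete imaging protocol: a 60 s dark baseline, three sub-milliwatt
#' steps, five effective heating steps (69.5, 178, 286.5, 395 and 532.5 mW,
#' 60 s each), and a final 120 s recovery with the laser off.
#'
#' @return A [power_protocol()] object spanning 0 to 660 s.
#' @export
nir_protocol_full <- function() {
  power_protocol(
    t_start = seq(0, 540, by = 60),
    t_end = c(seq(60, 540, by = 60), 660),
    power = c(0, 0.148e-3, 0.425e-3, 1e-3,
              69.5e-3, 178e-3, 286.5e-3, 395e-3, 532.5e-3, 0)
  )
}

#' The calibration window of the laser step law
#'
#' The four effective heating steps used for calibrating the absorption
#' fraction, with the clock re-zeroed at the onset of the 69.5 mW step.
#' The sub-milliwatt steps preceding it produce no measurable heating and the
#' last (532.5 mW) step shows saturation in the measurements, so model
#' integration for calibration stops at 240 s.
#'
#' @return A [power_protocol()] object spanning 0 to 240 s.
#' @export
nir_protocol_calibration <- function() {
  power_protocol(
    t_start = c(0, 60, 120, 180),
    t_end = c(60, 120, 180, 240),
    power = c(69.5e-3, 178e-3, 286.5e-3, 395e-3)
  )
}

#' Heat-source fractions of the nominal NIR power
#'
#' The fraction xi of nominal laser power acting as a heat source is factored
#' as `xi = xi_density * xi_abs`: the occupancy ("covering") fraction of the
#' irradiated region actually coated by particles, times the effective
#' absorption fraction of the particles themselves.
#'
#' @param xi_density Occupancy fraction, in (0, 1].
#' @param xi_abs Effective absorption fraction, in (0, 1).
#' @return An object of class `source_fractions` with elements `xi_density`,
#'   `xi_abs` and the derived product `xi`.
#' @export
#' @examples
#' source_fractions(0.17, 0.17)$xi
source_fractions <- function(xi_density, xi_abs) {
  if (!is.numeric(xi_density) || length(xi_density) != 1L ||
      xi_density <= 0 || xi_density > 1)
    stop("'xi_density' must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(xi_abs) || length(xi_abs) != 1L || xi_abs <= 0 || xi_abs >= 1)
    stop("'xi_abs' must lie in (0, 1)", call. = FALSE)
  xi <- xi_density * xi_abs
  if (xi <= 0 || xi >= 1)
    stop("the product xi = xi_density * xi_abs must lie in (0, 1)", call. = FALSE)
  structure(list(xi_density = xi_density, xi_abs = xi_abs, xi = xi),
            class = "source_fractions")
}

#' @export
print.source_fractions <- function(x, ...) {
  cat(sprintf("Source fractions: xi_density = %g, xi_abs = %g, xi = %g\n",
              x$xi_density, x$xi_abs, x$xi))
  invisible(x)
}

#' Nominal NIR intensity at a point and time
#'
#' The nominal intensity is `P_NIR(t) / (pi * spot_radius^2)` inside the
#' irradiation spot (0 <= r <= spot_radius) and zero outside
#' (spot_radius < r <= domain_radius); piecewise constant in time following
#' the protocol.
#'
#' @param protocol A [power_protocol()] object.
#' @param params A [thermal_params()] object.
#' @param r Radial positions, m (vectorised).
#' @param t A single time, s, within the protocol span.
#' @return Intensity, W m-2, one value per element of `r`.
#' @export
#' @examples
#' p <- thermal_params()
#' nir_intensity(nir_protocol_full(), p, r = 0, t = 500)
nir_intensity <- function(protocol, params, r, t) {
  stopifnot(inherits(params, "thermal_params"), length(t) == 1L)
  if (any(r < 0 | r > params$domain_radius))
    stop("r must lie in [0, domain_radius]", call. = FALSE)
  P <- power_at(protocol, t)
  ifelse(r <= params$spot_radius, P / (pi * params$spot_radius^2), 0)
}
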