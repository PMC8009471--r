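#' Solve the axisymmetric heating problem by the method of lines
#'
#' Integrates the temperature increment \eqn{\Delta T(r, t)} of the irradiated
#' substrate under a laser step protocol. Space is discretized with
#' second-order centered finite differences on a uniform radial grid; the
#' symmetry condition at r = 0 uses the standard limit of the axisymmetric
#' Laplacian (2 d2T/dr2 with a ghost node), and the far-field boundary holds
#' the outer node at the ambient temperature. The resulting linear ODE system
#' is stiff and is advanced with an adaptive stiff integrator (lsoda, banded
#' Jacobian); the source, discontinuous at the spot edge, takes the mean of
#' its inside and outside values at the interface node, which preserves
#' second-order spatial accuracy.
#'
#' Integration restarts at every protocol segment boundary so the
#' discontinuous-in-time source is never smoothed across a step.
#'
#' @param params A [thermal_params()] object.
#' @param fractions A [source_fractions()] object.
#' @param protocol A [power_protocol()] object.
#' @param grid A [radial_grid()] object (default 241 nodes).
#' @param t_end Final time, s; defaults to the protocol span.
#' @param times Output times, s; default: every second from 0 to `t_end` plus
#'   all segment boundaries.
#' @param time_scale Reference-time choice, see [build_nondimensional()];
#'   dimensional output is invariant to it.
#' @param rtol,atol Relative tolerance and absolute tolerance (K) of the time
#'   integrator.
#' @param far_field_tol Tolerance (K) for the far-field working assumption;
#'   exceeding it records a warning in the result.
#' @return An object of class `temperature_field`: list with `times` (s),
#'   `radii` (m), `delta_T` (K, matrix time x radius), `far_field_max` (K, the
#'   largest boundary-node increment), `edge_adjacent_max` (K, the largest
#'   increment at the node next to the boundary, reported to document how
#'   unperturbed the far field actually is), `params`, `fractions`, `protocol`,
#'   `grid`, and `warnings`.
#' @seealso [center_trace()], [steady_state_closed_form()],
#'   [energy_balance_residual()]
#' @export
#' @examples
#' fld <- solve_temperature(thermal_params(), source_fractions(0.17, 0.17),
#'                          nir_protocol_calibration(),
#'                          grid = radial_grid(thermal_params(), 49),
#'                          times = c(0, 60))
#' max(fld$delta_T)
solve_temperature <- function(params, fractions, protocol,
                              grid = radial_grid(params),
                              t_end = protocol_span(protocol),
                              times = NULL,
                              time_scale = c("diffusive", "exchange"),
                              rtol = 1e-6, atol = 1e-9,
                              far_field_tol = 1e-3) {
  stopifnot(inherits(params, "thermal_params"),
            inherits(fractions, "source_fractions"),
            inherits(protocol, "power_protocol"),
            inherits(grid, "radial_grid"))
  time_scale <- match.arg(time_scale)
  if (t_end <= 0 || t_end > protocol_span(protocol) + 1e-9)
    stop("'t_end' must lie within the protocol span", call. = FALSE)
  if (is.null(times)) {
    times <- sort(unique(c(seq(0, t_end, by = 1), t_end,
                           protocol$t_end[protocol$t_end < t_end])))
  } else {
    times <- sort(unique(as.numeric(times)))
    if (min(times) < 0 || max(times) > t_end + 1e-9)
      stop("'times' must lie within [0, t_end]", call. = FALSE)
    if (times[1L] > 0) times <- c(0, times)
  }

  scheme <- build_nondimensional(params, fractions, time_scale)
  rbar <- grid$radii / scheme$length_ref
  d <- rbar[2L] - rbar[1L]
  n <- grid$n_nodes
  ni <- n - 1L                     # boundary node pinned at 0, not integrated

  # scaled source per unit power (W): sigma * I/P, with the interface-mean
  # convention at the spot-edge node
  src_unit <- numeric(n)
  src_unit[seq_len(grid$spot_index - 1L)] <- 1
  src_unit[grid$spot_index] <- 0.5
  src_unit <- src_unit * scheme$source_scale / (pi * params$spot_radius^2)

  alpha <- scheme$alpha
  omega <- scheme$omega
  xi <- scheme$xi
  inner <- 2:ni
  inv_d2 <- 1 / d^2
  inv_2dr <- 1 / (2 * d * rbar[inner])

  rhs <- function(t, y, p) {
    lap <- numeric(ni)
    lap[1L] <- 4 * (y[2L] - y[1L]) * inv_d2
    yp <- c(y[-1L], 0)
    ym <- y[inner - 1L]
    lap[inner] <- (yp[inner] - 2 * y[inner] + ym) * inv_d2 +
      (yp[inner] - ym) * inv_2dr
    list(alpha * (lap - omega * y + p))
  }

  atol_bar <- atol / params$ambient
  y <- numeric(ni)
  out_T <- matrix(0, nrow = length(times), ncol = n)
  seg <- protocol[protocol$t_start < t_end, , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    a0 <- seg$t_start[i]
    b0 <- min(seg$t_end[i], t_end)
    src <- xi * seg$power[i] * src_unit[seq_len(ni)]
    want <- which(times > a0 + 1e-12 & times <= b0 + 1e-12)
    tt <- sort(unique(c(a0, times[want], b0)))
    sol <- deSolve::ode(y = y, times = nondim_time(scheme, tt), func = rhs,
                        parms = src, method = "lsoda",
                        jactype = "bandint", bandup = 1L, banddown = 1L,
                        rtol = rtol, atol = atol_bar)
    if (attr(sol, "istate")[1L] < 0)
      stop("time integrator failed to converge on segment ", i, call. = FALSE)
    Tb <- sol[, -1L, drop = FALSE]
    if (length(want))
      out_T[want, seq_len(ni)] <- Tb[match(times[want], tt), , drop = FALSE]
    y <- Tb[nrow(Tb), ]
    if (b0 >= t_end) break
  }
  delta_T <- dim_temperature(scheme, out_T)
  if (!all(is.finite(delta_T)))
    stop("solver produced non-finite temperatures", call. = FALSE)

  warnings <- character()
  far_field_max <- max(abs(delta_T[, n]))
  edge_adjacent_max <- max(abs(delta_T[, n - 1L]))
  if (far_field_max > far_field_tol) {
    warnings <- c(warnings, sprintf(
      "far-field working assumption violated: max |dT(r_inf, t)| = %g K > %g K",
      far_field_max, far_field_tol))
    warning(warnings[length(warnings)], call. = FALSE)
  }

  structure(list(
    times = times, radii = grid$radii, delta_T = delta_T,
    far_field_max = far_field_max, edge_adjacent_max = edge_adjacent_max,
    params = params, fractions = fractions, protocol = protocol, grid = grid,
    time_scale = time_scale, rtol = rtol, atol = atol, warnings = warnings
  ), class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("Temperature field: %d times in [0, %g] s x %d radii in [0, %g] mm\n",
              length(x$times), max(x$times), length(x$radii),
              1e3 * max(x$radii)))
  cat(sprintf("  max dT: %.4g K (center, t = %g s); far-field max |dT|: %.3g K\n",
              max(x$delta_T), x$times[which.max(x$delta_T[, 1L])],
              x$far_field_max))
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n   ")
  invisible(x)
}

#' @export
as.data.frame.temperature_field <- function(x, ...) {
  data.frame(
    time = rep(x$times, times = length(x$radii)),
    radius = rep(x$radii, each = length(x$times)),
    delta_T = as.vector(x$delta_T)
  )
}

#' Center-spot temperature-increment trace
#'
#' Extracts \eqn{\Delta T(r = 0, t)} on the field's time base.
#'
#' @param field A `temperature_field` from [solve_temperature()].
#' @return A data frame with columns `time` (s) and `delta_T` (K).
#' @export
center_trace <- function(field) {
  stopifnot(inherits(field, "temperature_field"))
  data.frame(time = field$times, delta_T = field$delta_T[, 1L])
}

#' Write a temperature field as a long-format CSV
#'
#' Columns `time` (s), `radius` (m), `delta_T` (K).
#'
#' @param field A `temperature_field`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_temperature_field <- function(field, path) {
  stopifnot(inherits(field, "temperature_field"))
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}
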