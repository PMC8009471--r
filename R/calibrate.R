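#' Reference step-end temperature observations
#'
#' The four intracellular step-end temperature increments used to calibrate
#' the effective absorption fraction: means and standard errors measured at
#' the center of the irradiation spot at the end of the 69.5, 178, 286.5 and
#' 395 mW steps (clock zeroed at the onset of the 69.5 mW step).
#'
#' @return A data frame with columns `power` (W), `t_obs` (s),
#'   `delta_T_mean` (K) and `delta_T_se` (K).
#' @export
#' @examples
#' reference_observations()
reference_observations <- function() {
  path <- system.file("extdata", "reference_step_observations.csv",
                      package = "nirheat", mustWork = TRUE)
  read_observations(path)
}

validate_observations <- function(observations) {
  req <- c("power", "t_obs", "delta_T_mean", "delta_T_se")
  if (!is.data.frame(observations) || !all(req %in% names(observations)))
    stop("observations must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (nrow(observations) < 1L)
    stop("at least one observation is required", call. = FALSE)
  if (any(observations$delta_T_se <= 0))
    stop("'delta_T_se' must be positive", call. = FALSE)
  observations
}

#' Calibrate the effective absorption fraction
#'
#' Estimates the effective absorption fraction `xi_abs` of the particles by
#' least squares: the forward model's center-spot temperature increment is
#' evaluated at each observation time and the sum of squared residuals against
#' the observed means is minimized over `xi_abs` by bounded scalar
#' minimization. Because the governing equation is linear in the source
#' fraction, predictions are strictly increasing (in fact proportional) in
#' `xi_abs`, so the one-dimensional least-squares problem has a unique
#' minimum; internally the model is solved once at a reference fraction and
#' rescaled, which makes repeated fits on identical inputs bit-identical.
#'
#' Residuals are unweighted by default; `weighted = TRUE` weights them by the
#' reciprocal squared standard errors.
#'
#' @param observations Data frame with columns `power` (W), `t_obs` (s),
#'   `delta_T_mean` (K), `delta_T_se` (K); see [reference_observations()].
#' @param params A [thermal_params()] object.
#' @param protocol A [power_protocol()] object covering all `t_obs`.
#' @param xi_density Occupancy fraction of the irradiated region, in (0, 1].
#' @param bounds Search interval for `xi_abs`, inside (0, 1).
#' @param weighted Weight residuals by 1/se^2 (default FALSE).
#' @param grid A [radial_grid()] object.
#' @param tol Convergence tolerance of the scalar minimizer.
#' @param rtol,atol Forward-solver tolerances, see [solve_temperature()].
#' @return An object of class `absorption_fit` with elements `xi_abs`, `rmse`
#'   (K, unweighted), `predictions` (K), `converged` (FALSE when the optimum
#'   sits on a search bound), `observations`, and the model ingredients.
#' @seealso [coef.absorption_fit()], [predict.absorption_fit()],
#'   [simulate.absorption_fit()], [check_absorption_bound()]
#' @export
#' @examples
#' \donttest{
#' fit <- fit_absorption_fraction(reference_observations())
#' coef(fit)
#' summary(fit)
#' }
fit_absorption_fraction <- function(observations,
                                    params = thermal_params(),
                                    protocol = nir_protocol_calibration(),
                                    xi_density = 0.17,
                                    bounds = c(1e-6, 1 - 1e-6),
                                    weighted = FALSE,
                                    grid = radial_grid(params),
                                    tol = 1e-10,
                                    rtol = 1e-8, atol = 1e-11) {
  observations <- validate_observations(observations)
  stopifnot(inherits(params, "thermal_params"),
            inherits(protocol, "power_protocol"))
  if (xi_density <= 0 || xi_density > 1)
    stop("'xi_density' must lie in (0, 1]", call. = FALSE)
  if (length(bounds) != 2L || bounds[1L] <= 0 || bounds[2L] >= 1 ||
      bounds[1L] >= bounds[2L])
    stop("'bounds' must be an increasing pair inside (0, 1)", call. = FALSE)
  span <- protocol_span(protocol)
  if (any(observations$t_obs <= 0 | observations$t_obs > span + 1e-9))
    stop("observation times must lie within the integrated window (0, ",
         span, "] s", call. = FALSE)

  # unit response: center dT at the observation times per unit xi_abs
  xi_ref <- 0.5
  fld <- solve_temperature(params, source_fractions(xi_density, xi_ref),
                           protocol, grid = grid,
                           times = sort(unique(observations$t_obs)),
                           rtol = rtol, atol = atol)
  tr <- center_trace(fld)
  unit <- tr$delta_T[match(observations$t_obs, tr$time)] / xi_ref

  y <- observations$delta_T_mean
  w <- if (weighted) 1 / observations$delta_T_se^2 else rep(1, length(y))
  sse <- function(x) sum(w * (y - x * unit)^2)
  opt <- stats::optimize(sse, interval = bounds, tol = tol)
  xi_abs <- opt$minimum
  converged <- (xi_abs - bounds[1L]) > 10 * tol &&
    (bounds[2L] - xi_abs) > 10 * tol
  predictions <- xi_abs * unit

  structure(list(
    xi_abs = xi_abs,
    rmse = rmse(predictions, y),
    predictions = predictions,
    converged = converged,
    observations = observations,
    unit_response = unit,
    xi_density = xi_density,
    weighted = weighted,
    bounds = bounds,
    params = params, protocol = protocol, grid = grid,
    rtol = rtol, atol = atol
  ), class = "absorption_fit")
}

#' Root-mean-square error
#'
#' @param predictions,observations Numeric vectors of equal length.
#' @return Root-mean-square of the pairwise differences (same units as the
#'   inputs).
#' @export
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt((9 + 16) / 2)
rmse <- function(predictions, observations) {
  if (length(predictions) != length(observations) || length(predictions) < 1L)
    stop("'predictions' and 'observations' must have equal length >= 1",
         call. = FALSE)
  sqrt(mean((predictions - observations)^2))
}

#' Transmittance-derived upper bound on the absorption fraction
#'
#' The effective absorption fraction cannot exceed the fraction of light not
#' transmitted: the check passes iff `xi_abs < 1 - transmittance` (strict).
#'
#' @param xi_abs Effective absorption fraction.
#' @param transmittance Measured transmittance coefficient, in (0, 1).
#' @return A list with `pass` (logical), `bound` (`1 - transmittance`) and
#'   `margin` (`bound - xi_abs`).
#' @export
#' @examples
#' check_absorption_bound(0.17, 0.75)
check_absorption_bound <- function(xi_abs, transmittance) {
  stopifnot(is.numeric(xi_abs), length(xi_abs) == 1L,
            is.numeric(transmittance), length(transmittance) == 1L)
  if (transmittance <= 0 || transmittance >= 1)
    stop("'transmittance' must lie in (0, 1)", call. = FALSE)
  bound <- 1 - transmittance
  list(pass = xi_abs < bound, bound = bound, margin = bound - xi_abs)
}

#' @export
print.absorption_fit <- function(x, ...) {
  cat("Calibrated NIR absorption fraction\n")
  cat(sprintf("  xi_abs = %.4f (xi_density = %g, xi = %.4f)%s\n",
              x$xi_abs, x$xi_density, x$xi_abs * x$xi_density,
              if (x$converged) "" else "  [NOT converged: optimum on a bound]"))
  cat(sprintf("  RMSE = %.3f K over %d step-end observation(s)\n",
              x$rmse, nrow(x$observations)))
  invisible(x)
}

#' @export
coef.absorption_fit <- function(object, ...) c(xi_abs = object$xi_abs)

#' @export
fitted.absorption_fit <- function(object, ...) object$predictions

#' @export
residuals.absorption_fit <- function(object, ...) {
  object$observations$delta_T_mean - object$predictions
}

#' Predict the center-spot temperature increment of a calibrated model
#'
#' Re-evaluates the forward model at the fitted absorption fraction. Because
#' the model is linear in the source fraction, this scales the stored unit
#' response when `times` match the observation times, and re-solves otherwise.
#'
#' @param object An `absorption_fit`.
#' @param times Times, s (default: the observation times).
#' @param ... Unused.
#' @return A data frame with columns `time` and `delta_T` (K).
#' @export
predict.absorption_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$observations$t_obs
  fld <- solve_temperature(object$params,
                           source_fractions(object$xi_density, object$xi_abs),
                           object$protocol, grid = object$grid,
                           times = sort(unique(times[times > 0])),
                           rtol = object$rtol, atol = object$atol)
  tr <- center_trace(fld)
  data.frame(time = times,
             delta_T = tr$delta_T[match(times, tr$time)])
}

#' @export
summary.absorption_fit <- function(object, ...) {
  obs <- object$observations
  tab <- data.frame(
    power_mW = 1e3 * obs$power,
    t_s = obs$t_obs,
    observed_K = obs$delta_T_mean,
    se_K = obs$delta_T_se,
    predicted_K = object$predictions,
    residual_K = obs$delta_T_mean - object$predictions
  )
  structure(list(xi_abs = object$xi_abs, xi_density = object$xi_density,
                 rmse = object$rmse, converged = object$converged,
                 weighted = object$weighted, table = tab),
            class = "summary.absorption_fit")
}

#' @export
print.summary.absorption_fit <- function(x, ...) {
  cat("Calibration of the effective NIR absorption fraction\n\n")
  cat(sprintf("  xi_abs    = %.4f%s\n", x$xi_abs,
              if (x$converged) "" else "  [NOT converged]"))
  cat(sprintf("  xi        = xi_density * xi_abs = %g * %.4f = %.4f\n",
              x$xi_density, x$xi_abs, x$xi_density * x$xi_abs))
  cat(sprintf("  RMSE      = %.3f K (%s least squares)\n\n",
              x$rmse, if (x$weighted) "1/se^2-weighted" else "unweighted"))
  print.data.frame(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Plot a calibrated fit
#'
#' Draws the calibrated model's center-spot trace with the step-end
#' observations and their standard-error bars.
#'
#' @param x An `absorption_fit`.
#' @param step Time resolution of the plotted model trace, s.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.absorption_fit <- function(x, step = 2, ...) {
  span <- protocol_span(x$protocol)
  tr <- predict(x, times = seq(0, span, by = step))
  obs <- x$observations
  ylim <- range(0, tr$delta_T, obs$delta_T_mean + obs$delta_T_se)
  graphics::plot(tr$time, tr$delta_T, type = "l", lwd = 2, ylim = ylim,
                 xlab = "time (s)", ylab = expression(Delta * T ~ "(K)"), ...)
  graphics::points(obs$t_obs, obs$delta_T_mean, pch = 19)
  graphics::arrows(obs$t_obs, obs$delta_T_mean - obs$delta_T_se,
                   obs$t_obs, obs$delta_T_mean + obs$delta_T_se,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Simulate observation sets from a calibrated model
#'
#' Draws synthetic step-end observation sets from the fitted model with
#' additive Gaussian noise, mirroring the measurement design.
#'
#' @param object An `absorption_fit`.
#' @param nsim Number of replicate observation sets.
#' @param seed Optional integer seed; the RNG state is restored on exit.
#' @param noise_sd Noise standard deviation, K (default: the mean observed
#'   standard error).
#' @param ... Unused.
#' @return A list of `nsim` observation data frames.
#' @export
simulate.absorption_fit <- function(object, nsim = 1, seed = NULL,
                                    noise_sd = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (is.null(noise_sd)) noise_sd <- mean(object$observations$delta_T_se)
  truth <- object$predictions
  lapply(seq_len(nsim), function(i) {
    out <- object$observations
    out$delta_T_mean <- truth + stats::rnorm(length(truth), sd = noise_sd)
    out$delta_T_se <- rep(max(noise_sd, 1e-12), length(truth))
    out
  })
}
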