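#' Specification of the synthetic-data generators
#'
#' Collects everything the generators need to emulate the study's measurement
#' conditions with known ground truth: forward-model settings, the 15 s
#' imaging cadence, the additive noise scale matched to the reported
#' standard errors (0.2-0.94 K, mid-range 0.3 K), and image-generation
#' settings.
#'
#' @param seed Integer seed; fixed seed implies bit-identical outputs.
#' @param xi_abs_true Ground-truth effective absorption fraction.
#' @param xi_density Occupancy fraction used by the forward model.
#' @param noise_sd Additive noise standard deviation on temperature
#'   observations, K.
#' @param cadence Sampling interval of the imaging, s.
#' @param protocol A [power_protocol()] object.
#' @param params A [thermal_params()] object.
#' @param image_size Side length of generated square images, px.
#' @param coverage_true Ground-truth particle coverage fraction.
#' @param axis_ratios Minor/major axis ratios of generated ellipse masks.
#' @return An object of class `synthetic_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       xi_abs_true = 0.17,
                       xi_density = 0.17,
                       noise_sd = 0.3,
                       cadence = 15,
                       protocol = nir_protocol_calibration(),
                       params = thermal_params(),
                       image_size = 256L,
                       coverage_true = 0.17,
                       axis_ratios = c(0.25, 0.5, 0.75, 1)) {
  stopifnot(inherits(protocol, "power_protocol"),
            inherits(params, "thermal_params"))
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  if (cadence <= 0) stop("'cadence' must be positive", call. = FALSE)
  if (coverage_true < 0 || coverage_true > 1)
    stop("'coverage_true' must lie in [0, 1]", call. = FALSE)
  if (any(axis_ratios <= 0 | axis_ratios > 1))
    stop("'axis_ratios' must lie in (0, 1]", call. = FALSE)
  structure(list(seed = as.integer(seed), xi_abs_true = xi_abs_true,
                 xi_density = xi_density, noise_sd = noise_sd,
                 cadence = cadence, protocol = protocol, params = params,
                 image_size = as.integer(image_size),
                 coverage_true = coverage_true, axis_ratios = axis_ratios),
            class = "synthetic_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic step-end temperature observations
#'
#' Runs the forward model at the ground-truth absorption fraction, samples
#' the center-spot trace at the imaging cadence, adds independent Gaussian
#' noise, and emits one observation per protocol segment with positive power:
#' the noisy sample at the segment end, with the empirical noise scale
#' (standard deviation of the within-segment residuals about the noiseless
#' model) as its standard error. With `noise_sd = 0` the observations equal
#' the model predictions exactly (standard errors floored at a tiny positive
#' value to respect their positivity invariant).
#'
#' @param spec A [synth_spec()].
#' @return A list with `observations` (data frame: `power`, `t_obs`,
#'   `delta_T_mean`, `delta_T_se`), `trace` (data frame: `time`,
#'   `delta_T_true`, `delta_T_noisy`) and `truth` (list with `xi_abs_true`,
#'   `xi_density`, `noise_sd`).
#' @export
synth_temperature_observations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  span <- protocol_span(spec$protocol)
  times <- sort(unique(c(seq(spec$cadence, span, by = spec$cadence),
                         spec$protocol$t_end)))
  fld <- solve_temperature(spec$params,
                           source_fractions(spec$xi_density, spec$xi_abs_true),
                           spec$protocol, times = times,
                           rtol = 1e-8, atol = 1e-11)
  tr <- center_trace(fld)
  tr <- tr[tr$time > 0, ]
  noisy <- with_seed(spec$seed,
                     tr$delta_T + stats::rnorm(nrow(tr), sd = spec$noise_sd))
  seg <- spec$protocol[spec$protocol$power > 0, , drop = FALSE]
  obs <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
    sel <- tr$time > seg$t_start[i] & tr$time <= seg$t_end[i]
    end <- which(tr$time == seg$t_end[i])
    se <- stats::sd(noisy[sel] - tr$delta_T[sel])
    if (!is.finite(se) || se == 0) se <- max(spec$noise_sd, 1e-12)
    data.frame(power = seg$power[i], t_obs = seg$t_end[i],
               delta_T_mean = noisy[end], delta_T_se = se)
  }))
  list(observations = obs,
       trace = data.frame(time = tr$time, delta_T_true = tr$delta_T,
                          delta_T_noisy = noisy),
       truth = list(xi_abs_true = spec$xi_abs_true,
                    xi_density = spec$xi_density, noise_sd = spec$noise_sd))
}

#' Synthetic fluorescence trace
#'
#' Applies the inverse thermometry conversion to the noiseless synthetic
#' center-spot temperature trace and multiplies by log-free Gaussian noise
#' whose scale corresponds, through the conversion slope, to `noise_sd`
#' kelvin. Round-tripping the noiseless trace through the thermometry module
#' recovers the temperature trace exactly.
#'
#' @param spec A [synth_spec()].
#' @param constants A [conversion_constants()] object.
#' @return A list with `trace` (a [fluorescence_trace()] of F/F0 values,
#'   baseline window degenerate at t = 0 where the increment is zero) and
#'   `delta_T_true` (degC, same time base).
#' @export
synth_fluorescence_trace <- function(spec, constants = conversion_constants()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  span <- protocol_span(spec$protocol)
  times <- sort(unique(c(0, seq(spec$cadence, span, by = spec$cadence),
                         spec$protocol$t_end)))
  fld <- solve_temperature(spec$params,
                           source_fractions(spec$xi_density, spec$xi_abs_true),
                           spec$protocol, times = times,
                           rtol = 1e-8, atol = 1e-11)
  tr <- center_trace(fld)
  f_true <- delta_T_to_fluorescence(tr$delta_T, constants)
  sd_mult <- spec$noise_sd * constants$decrement_per_degree / 100
  f <- with_seed(spec$seed + 1L,
                 f_true * (1 + stats::rnorm(length(f_true), sd = sd_mult)))
  f <- pmax(f, 1e-6)
  first <- min(tr$time[tr$delta_T > 1e-9], protocol_span(spec$protocol))
  list(trace = fluorescence_trace(tr$time, f,
                                  baseline_window = c(0, max(0, first - 1e-9))),
       delta_T_true = tr$delta_T)
}

#' Synthetic particle-coverage image
#'
#' Scatters non-overlapping bright disks on a dark background until the
#' requested pixel coverage is reached, trimming the outermost pixels of the
#' last disk so the realized foreground count matches
#' `round(coverage * image_size^2)` exactly. Mild Gaussian intensity noise is
#' added to both classes (background about 0.1, foreground about 0.85) so
#' automatic thresholding has realistic work to do; a fixed threshold of 0.5
#' separates the classes exactly.
#'
#' @param spec A [synth_spec()].
#' @param radius_range Disk radius range, px.
#' @return An object of class `particle_image`: list with `pixels` (matrix),
#'   `mask` (logical ground-truth foreground), `coverage` (realized fraction)
#'   and `n_disks`.
#' @export
synth_particle_image <- function(spec, radius_range = c(4, 9)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$image_size
  target_px <- round(spec$coverage_true * n^2)
  if (spec$coverage_true > 0.35)
    stop("requested coverage exceeds the non-overlapping packing limit",
         call. = FALSE)
  with_seed(spec$seed + 2L, {
    mask <- matrix(FALSE, n, n)
    centers <- matrix(numeric(0), 0, 3)  # x, y, r
    last_disk <- NULL
    tries <- 0L
    while (sum(mask) < target_px) {
      if (tries > 20000L)
        stop("could not reach requested coverage without overlap", call. = FALSE)
      r <- stats::runif(1, radius_range[1L], radius_range[2L])
      cx <- stats::runif(1, r + 1, n - r)
      cy <- stats::runif(1, r + 1, n - r)
      tries <- tries + 1L
      if (nrow(centers) > 0 &&
          any((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 <
              (centers[, 3] + r + 1)^2)) next
      xs <- max(1L, floor(cx - r)):min(n, ceiling(cx + r))
      ys <- max(1L, floor(cy - r)):min(n, ceiling(cy + r))
      px <- expand.grid(x = xs, y = ys)
      d2 <- (px$x - cx)^2 + (px$y - cy)^2
      inside <- px[d2 <= r^2, ]
      if (nrow(inside) == 0L) next
      centers <- rbind(centers, c(cx, cy, r))
      idx <- cbind(inside$x, inside$y)
      new <- idx[!mask[idx], , drop = FALSE]
      mask[new] <- TRUE
      last_disk <- list(idx = new, cx = cx, cy = cy)
    }
    excess <- sum(mask) - target_px
    if (excess > 0L && !is.null(last_disk)) {
      d2 <- (last_disk$idx[, 1] - last_disk$cx)^2 +
        (last_disk$idx[, 2] - last_disk$cy)^2
      drop <- last_disk$idx[order(-d2)[seq_len(excess)], , drop = FALSE]
      mask[drop] <- FALSE
    }
    pixels <- matrix(stats::rnorm(n^2, mean = 0.1, sd = 0.02), n, n)
    pixels[mask] <- stats::rnorm(sum(mask), mean = 0.85, sd = 0.02)
    pixels <- pmin(pmax(pixels, 0), 1)
    structure(list(pixels = pixels, mask = mask,
                   coverage = sum(mask) / n^2,
                   n_disks = nrow(centers)),
              class = "particle_image")
  })
}

#' Synthetic labeled ellipse masks
#'
#' Rasterizes one filled ellipse per requested axis ratio at a random
#' orientation, as a stand-in for labeled mitochondrial masks with known
#' ground-truth shape. Ellipses are placed on a shuffled grid of
#' non-overlapping cells with random jitter inside each cell, so regions can
#' never touch and generation never rejects. Moment-based region measurement
#' recovers `minor/major = ratio` within rasterization error.
#'
#' @param spec A [synth_spec()].
#' @param semi_major Ellipse semi-major axis, px.
#' @return A list with `mask` (integer label matrix) and `truth` (data frame:
#'   `label`, `axis_ratio`, `orientation`).
#' @export
synth_ellipse_masks <- function(spec, semi_major = 22) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$image_size
  ratios <- spec$axis_ratios
  margin <- semi_major + 2
  cell <- 2 * margin
  per_side <- n %/% cell
  if (per_side^2 < length(ratios))
    stop("'image_size' too small for the requested ellipses", call. = FALSE)
  with_seed(spec$seed + 3L, {
    mask <- matrix(0L, n, n)
    truth <- data.frame(label = integer(0), axis_ratio = numeric(0),
                        orientation = numeric(0))
    cells <- sample(per_side^2)[seq_along(ratios)]
    jitter_max <- cell / 2 - margin
    for (i in seq_along(ratios)) {
      row <- (cells[i] - 1L) %/% per_side
      col <- (cells[i] - 1L) %% per_side
      cx <- row * cell + cell / 2 + stats::runif(1, -jitter_max, jitter_max)
      cy <- col * cell + cell / 2 + stats::runif(1, -jitter_max, jitter_max)
      theta <- stats::runif(1, 0, pi)
      a <- semi_major
      b <- semi_major * ratios[i]
      xs <- max(1L, floor(cx - margin)):min(n, ceiling(cx + margin))
      ys <- max(1L, floor(cy - margin)):min(n, ceiling(cy + margin))
      px <- expand.grid(x = xs, y = ys)
      dx <- px$x - cx; dy <- px$y - cy
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      mask[cbind(px$x[inside], px$y[inside])] <- i
      truth <- rbind(truth, data.frame(label = i, axis_ratio = ratios[i],
                                       orientation = theta))
    }
    list(mask = mask, truth = truth)
  })
}
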