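#' Particle occupancy fraction of a grayscale image
#'
#' Binarizes a grayscale image and returns the foreground pixel fraction,
#' the "covering/occupancy" fraction of the field of view coated by
#' particles. The default threshold is Otsu's method (via EBImage) computed on
#' the intensity range of the image; a fixed threshold on the raw intensities
#' is available for reproducibility against synthetic ground truth.
#'
#' @param image A numeric matrix of intensities (at least 16 x 16), or a
#'   `particle_image` from [synth_particle_image()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Threshold value for `method = "fixed"`; pixels strictly
#'   above it are foreground.
#' @return Foreground fraction in \[0, 1\].
#' @export
#' @examples
#' img <- matrix(0.1, 32, 32); img[8:16, 8:16] <- 0.9
#' occupancy_fraction(img, method = "fixed", threshold = 0.5)
occupancy_fraction <- function(image, method = c("otsu", "fixed"),
                               threshold = NULL) {
  if (inherits(image, "particle_image")) image <- image$pixels
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 16L || ncol(image) < 16L)
    stop("'image' must be at least 16 x 16 pixels", call. = FALSE)
  if (!all(is.finite(image)))
    stop("'image' must contain finite intensities", call. = FALSE)
  if (method == "fixed") {
    if (is.null(threshold))
      stop("'threshold' is required when method = \"fixed\"", call. = FALSE)
  } else {
    rng <- range(image)
    if (diff(rng) == 0)
      stop("constant image: automatic thresholding cannot separate classes",
           call. = FALSE)
    scaled <- (image - rng[1L]) / diff(rng)
    threshold <- rng[1L] +
      diff(rng) * EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  }
  mean(image > threshold)
}

#' Shape measurements of labeled regions
#'
#' Measures each labeled region of an integer mask: pixel area and the major
#' and minor axis lengths of the intensity-moment (best-fit) ellipse, as
#' computed by EBImage.
#'
#' @param mask An integer matrix; 0 is background, positive values label
#'   regions.
#' @return A data frame with columns `label`, `area` (px^2), `major_axis` and
#'   `minor_axis` (px).
#' @export
region_shapes <- function(mask) {
  if (!is.matrix(mask) || any(mask < 0) || any(mask != round(mask)))
    stop("'mask' must be a matrix of non-negative integer labels",
         call. = FALSE)
  labels <- sort(unique(mask[mask > 0]))
  if (length(labels) == 0L)
    stop("'mask' contains no labeled regions", call. = FALSE)
  m <- EBImage::computeFeatures.moment(mask)
  s <- EBImage::computeFeatures.shape(mask)
  major <- m[, "m.majoraxis"]
  minor <- major * sqrt(1 - m[, "m.eccentricity"]^2)
  data.frame(label = labels, area = as.numeric(s[, "s.area"]),
             major_axis = as.numeric(major), minor_axis = as.numeric(minor),
             row.names = NULL)
}

#' Roundness of a region
#'
#' The ImageJ roundness of a region with the best-fit-ellipse major axis:
#' `4 * area / (pi * major_axis^2)`, a value in (0, 1\] that equals 1 for a
#' circle and `minor/major` for an ellipse. Values marginally above 1 from
#' rasterization jitter are clipped to 1. Because the direction of published
#' roundness scales is not always unambiguous, `convention = "complement"`
#' returns `1 - roundness` instead; analyses should state which convention
#' they use.
#'
#' @param shape A data frame with columns `area` and `major_axis` (e.g. from
#'   [region_shapes()]), or a named numeric vector with those elements.
#' @param convention `"roundness"` (default, ImageJ) or `"complement"`.
#' @return Roundness value(s) in (0, 1\].
#' @export
#' @examples
#' roundness(c(area = pi * 10^2, major_axis = 20))  # circle: 1
roundness <- function(shape, convention = c("roundness", "complement")) {
  convention <- match.arg(convention)
  if (is.numeric(shape)) shape <- as.data.frame(as.list(shape))
  if (!all(c("area", "major_axis") %in% names(shape)))
    stop("'shape' must provide 'area' and 'major_axis'", call. = FALSE)
  if (any(shape$major_axis <= 0))
    stop("'major_axis' must be positive", call. = FALSE)
  if (any(shape$area <= 0))
    stop("'area' must be positive", call. = FALSE)
  rho <- pmin(4 * shape$area / (pi * shape$major_axis^2), 1)
  if (convention == "complement") 1 - rho else rho
}

#' Summarize a set of roundness values
#'
#' Median roundness plus the fractions of regions in the three morphological
#' classes rho <= 0.3, 0.3 < rho <= 0.7 and 0.7 < rho <= 1 (upper edges
#' inclusive).
#'
#' @param values Roundness values in \[0, 1\].
#' @return An object of class `roundness_summary`: list with `median_rho`,
#'   `class_fractions` (named, summing to 1) and `n`.
#' @export
#' @examples
#' summarize_roundness(c(0.1, 0.3, 0.5, 0.7, 0.9))
summarize_roundness <- function(values) {
  if (length(values) < 1L)
    stop("'values' must be non-empty", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0 | values > 1))
    stop("roundness values must lie in [0, 1]", call. = FALSE)
  fr <- c(
    "rho<=0.3" = mean(values <= 0.3),
    "0.3<rho<=0.7" = mean(values > 0.3 & values <= 0.7),
    "0.7<rho<=1" = mean(values > 0.7)
  )
  structure(list(median_rho = stats::median(values), class_fractions = fr,
                 n = length(values)),
            class = "roundness_summary")
}

#' @export
print.roundness_summary <- function(x, ...) {
  cat(sprintf("Roundness of %d region(s): median rho = %.3f\n", x$n,
              x$median_rho))
  cat(sprintf("  classes: rho<=0.3: %.1f%%, 0.3<rho<=0.7: %.1f%%, 0.7<rho<=1: %.1f%%\n",
              100 * x$class_fractions[1L], 100 * x$class_fractions[2L],
              100 * x$class_fractions[3L]))
  invisible(x)
}

#' Transmittance from absorbance
#'
#' @param absorbance Absorbance, a.u. (>= 0), vectorised.
#' @return Transmittance `10^(-absorbance)`, dimensionless.
#' @export
#' @examples
#' transmittance_from_absorbance(0.125)  # about 0.75
transmittance_from_absorbance <- function(absorbance) {
  if (any(absorbance < 0))
    stop("'absorbance' must be non-negative", call. = FALSE)
  10^(-absorbance)
}

#' Read a grayscale image file as an intensity matrix
#'
#' Thin wrapper over [EBImage::readImage()] for TIFF/PNG input; multichannel
#' images are averaged to grayscale.
#'
#' @param path Image file path.
#' @return A numeric matrix of intensities.
#' @export
read_particle_image <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) > 2L) dat <- apply(dat, c(1L, 2L), mean)
  as.matrix(dat)
}
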