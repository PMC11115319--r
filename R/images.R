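#' Generate synthetic grayscale stimulus images
#'
#' Produces naturalistic-statistics stimuli: 1/f-filtered Gaussian noise mixed
#' with a few randomly oriented Gabor patches, affinely mapped to the 8-bit
#' range \[0, 255\] and rounded to integer intensities. The broadband spectrum
#' plus oriented energy drives both Gabor-bank and convolutional feature
#' cores, standing in for the grayscale natural images used in physiology
#' experiments.
#'
#' @param n number of images (>= 1).
#' @param size image side length in pixels (>= 16).
#' @param resolution nominal resolution in pixels per degree of visual angle,
#'   recorded as metadata for preprocessing.
#' @param n_gabors number of oriented Gabor patches superimposed per image.
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   images.
#' @return An object of class `image_set`: a list with `images`
#'   (`n x size x size` array of integers in \[0, 255\]), `image_size`,
#'   `resolution` and `seed`.
#' @examples
#' imgs <- sim_images(4, size = 32, seed = 1)
#' range(imgs$images)
#' @export
sim_images <- function(n, size = 64, resolution = 16, n_gabors = 3, seed = 1) {
  if (length(n) != 1L || n < 1) stop("`n` must be a positive count")
  if (length(size) != 1L || size < 16) stop("`size` must be >= 16 pixels")
  n <- as.integer(n)
  size <- as.integer(size)

  # radial frequency grid for the 1/f amplitude envelope
  fr <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  rad <- sqrt(outer(fr^2, fr^2, "+"))
  amp <- 1 / pmax(rad, 1 / size)

  imgs <- with_seed(seed, {
    out <- array(0, c(n, size, size))
    xy <- seq_len(size)
    for (i in seq_len(n)) {
      white <- matrix(stats::rnorm(size * size), size, size)
      img <- Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / (size * size)
      base_sd <- stats::sd(img)
      for (g in seq_len(n_gabors)) {
        theta <- stats::runif(1, 0, pi)
        freq <- stats::runif(1, 2, 6) / size       # cycles per pixel
        sig <- stats::runif(1, 0.08, 0.2) * size
        cx <- stats::runif(1, 0.25, 0.75) * size
        cy <- stats::runif(1, 0.25, 0.75) * size
        phase <- stats::runif(1, 0, 2 * pi)
        ampl <- stats::runif(1, 0.5, 1.5) * base_sd
        xr <- outer(rep(1, size), xy - cx)
        yr <- outer(xy - cy, rep(1, size))
        u <- xr * cos(theta) + yr * sin(theta)
        v <- -xr * sin(theta) + yr * cos(theta)
        img <- img + ampl * exp(-(u^2 + v^2) / (2 * sig^2)) *
          cos(2 * pi * freq * u + phase)
      }
      lo <- min(img); hi <- max(img)
      out[i, , ] <- round((img - lo) / (hi - lo) * 255)
    }
    out
  })

  structure(
    list(images = imgs, image_size = size, resolution = resolution, seed = seed),
    class = "image_set"
  )
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf(
    "<image_set> %d grayscale images, %dx%d px, %.3g px/deg, seed %d\n",
    dim(x$images)[1], x$image_size, x$image_size, x$resolution, x$seed
  ))
  invisible(x)
}

#' Specify cropping and resampling of stimulus images
#'
#' Defines the central crop (in degrees of visual angle) and the target
#' resolution at which images are presented to a feature core. The input
#' scale in px/deg is a model hyperparameter: it decouples receptive-field
#' size from feature complexity and is cross-validated like any other.
#'
#' @param crop_degrees visual-angle extent (deg) of the retained central crop.
#' @param source_resolution resolution of the source image, px/deg.
#' @param target_resolution resolution after resampling, px/deg.
#' @param interpolation `"bicubic"` (default, Keys a = -0.5, anti-aliased when
#'   downsampling) or `"bilinear"`.
#' @return An object of class `preprocess_spec`.
#' @examples
#' # a 420 px image at 63 px/deg: central 2.65 deg is a 167 px crop
#' spec <- preprocess_spec(2.65, 63, 14)
#' @export
preprocess_spec <- function(crop_degrees, source_resolution, target_resolution,
                            interpolation = c("bicubic", "bilinear")) {
  interpolation <- match.arg(interpolation)
  stopifnot(crop_degrees > 0, source_resolution > 0, target_resolution > 0)
  out_px <- max(1L, round(crop_degrees * target_resolution))
  structure(
    list(
      crop_degrees = crop_degrees,
      source_resolution = source_resolution,
      target_resolution = target_resolution,
      crop_px = round(crop_degrees * source_resolution),
      out_px = out_px,
      interpolation = interpolation
    ),
    class = "preprocess_spec"
  )
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat(sprintf(
    "<preprocess_spec> crop %.3g deg (%d px @ %.3g px/deg) -> %d px @ %.3g px/deg [%s]\n",
    x$crop_degrees, x$crop_px, x$source_resolution, x$out_px,
    x$target_resolution, x$interpolation
  ))
  invisible(x)
}

#' Crop and resample images for a feature core
#'
#' Takes the central crop of `crop_degrees` at the source resolution and
#' resamples it to the target resolution with the configured interpolation.
#'
#' @param images an `image_set`, a single `H x W` matrix, or an `n x H x W`
#'   array.
#' @param spec a [preprocess_spec()].
#' @return An `n x out x out` array (or a matrix if a single matrix was
#'   supplied).
#' @export
preprocess_image <- function(images, spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  single <- is.matrix(images)
  arr <- as_image_array(images)
  h <- dim(arr)[2]; w <- dim(arr)[3]
  cp <- spec$crop_px
  if (cp > h || cp > w) {
    stop(sprintf("crop of %d px does not fit inside a %dx%d image", cp, h, w))
  }
  r0 <- floor((h - cp) / 2)
  c0 <- floor((w - cp) / 2)
  rows <- (r0 + 1):(r0 + cp)
  cols <- (c0 + 1):(c0 + cp)
  out <- array(0, c(dim(arr)[1], spec$out_px, spec$out_px))
  wy <- resample_weights(cp, spec$out_px, spec$interpolation)
  for (i in seq_len(dim(arr)[1])) {
    out[i, , ] <- wy %*% arr[i, rows, cols] %*% t(wy)
  }
  if (single) out[1, , ] else out
}

# Keys cubic convolution kernel (a = -0.5).
keys_cubic <- function(x) {
  a <- -0.5
  ax <- abs(x)
  out <- numeric(length(x))
  i1 <- ax <= 1
  i2 <- ax > 1 & ax < 2
  out[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  out[i2] <- a * ax[i2]^3 - 5 * a * ax[i2]^2 + 8 * a * ax[i2] - 4 * a
  out
}

# Dense out x in resampling matrix for one separable dimension. When
# downsampling, the kernel support is widened by the scale factor
# (anti-aliasing), the standard approach for high-quality resizing.
resample_weights <- function(n_in, n_out, interpolation = "bicubic") {
  if (n_in == n_out) return(diag(n_in))
  scale <- n_in / n_out
  support <- max(1, scale)
  kern <- switch(interpolation,
    bicubic = function(x) keys_cubic(x / support),
    bilinear = function(x) pmax(0, 1 - abs(x / support)),
    stop("unknown interpolation: ", interpolation)
  )
  half <- if (interpolation == "bicubic") 2 * support else support
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    src <- (j - 0.5) * scale - 0.5          # 0-based source coordinate
    lo <- max(0L, floor(src - half))
    hi <- min(n_in - 1L, ceiling(src + half))
    idx <- lo:hi
    wts <- kern(src - idx)
    s <- sum(wts)
    if (s == 0) { wts <- rep(1 / length(idx), length(idx)) } else { wts <- wts / s }
    W[j, idx + 1L] <- wts
  }
  W
}
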