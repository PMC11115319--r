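# Frozen feature cores: image -> w x h x c feature maps. Cores are immutable
# during fitting; only the feature head (batch norm) and readouts are trained.

# "same" 2D convolution (correlation) of one image with one kernel, zero
# padded, via FFT. Kernel dims must be odd.
conv2d_same_fft <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  ph <- h + kh - 1L; pw <- w + kw - 1L
  pi_ <- matrix(0, ph, pw); pi_[1:h, 1:w] <- img
  pk <- matrix(0, ph, pw)
  # flip for correlation; place centered at origin with wrap
  k <- kernel[kh:1, kw:1]
  pk[1:kh, 1:kw] <- k
  full <- Re(stats::fft(stats::fft(pi_) * stats::fft(pk), inverse = TRUE)) / (ph * pw)
  # centered "same" crop of the full linear convolution
  full[((kh - 1L) %/% 2L + 1L):((kh - 1L) %/% 2L + h),
       ((kw - 1L) %/% 2L + 1L):((kw - 1L) %/% 2L + w)]
}

# Batched "same" correlation via shift-and-add, vectorized over the image
# axis. `stack` is n x H x W, kernel kh x kw (odd dims). Efficient for small
# kernels.
conv2d_same_shift <- function(stack, kernel) {
  d <- dim(stack)
  n <- d[1]; h <- d[2]; w <- d[3]
  kh <- nrow(kernel); kw <- ncol(kernel)
  cy <- (kh + 1L) %/% 2L; cx <- (kw + 1L) %/% 2L
  out <- array(0, d)
  for (a in seq_len(kh)) {
    dy <- a - cy
    ys <- max(1L, 1L + dy):min(h, h + dy)     # source rows
    yd <- ys - dy                              # destination rows
    for (b in seq_len(kw)) {
      wgt <- kernel[a, b]
      if (wgt == 0) next
      dx <- b - cx
      xs <- max(1L, 1L + dx):min(w, w + dx)
      xd <- xs - dx
      out[, yd, xd] <- out[, yd, xd] + wgt * stack[, ys, xs]
    }
  }
  out
}

# Replicate-pad the spatial dims of an n x H x W stack.
pad_replicate <- function(stack, oy, ox) {
  d <- dim(stack)
  ry <- clamp(seq_len(d[2] + 2L * oy) - oy, 1L, d[2])
  rx <- clamp(seq_len(d[3] + 2L * ox) - ox, 1L, d[3])
  stack[, ry, rx, drop = FALSE]
}

# "Same" correlation with replicate (edge) padding, so zero-mean filters
# respond with exact zeros to constant images everywhere, including map
# borders. FFT per image for large kernels, shift-add for small ones.
conv2d_same <- function(stack, kernel) {
  oy <- (nrow(kernel) - 1L) %/% 2L
  ox <- (ncol(kernel) - 1L) %/% 2L
  d <- dim(stack)
  p <- pad_replicate(stack, oy, ox)
  if (length(kernel) <= 49L) {
    full <- conv2d_same_shift(p, kernel)
  } else {
    full <- array(0, dim(p))
    for (i in seq_len(d[1])) full[i, , ] <- conv2d_same_fft(p[i, , ], kernel)
  }
  full[, oy + seq_len(d[2]), ox + seq_len(d[3]), drop = FALSE]
}

stride_index <- function(n, stride) seq.int(from = (stride + 1L) %/% 2L, to = n, by = stride)

#' Gabor filter bank feature core
#'
#' An analytically tractable stand-in for the early layers of a
#' convolutional network: a bank of zero-mean, unit-norm Gabor filters over a
#' grid of orientations, spatial frequencies and phases, applied as a "same"
#' convolution and spatially subsampled by `stride`. Core parameters are
#' frozen: repeated calls on the same input are identical.
#'
#' @param orientations number of evenly spaced orientations in \[0, pi).
#' @param frequencies spatial frequencies, cycles per pixel.
#' @param phases phase offsets in radians.
#' @param kernel_size odd filter side length in pixels.
#' @param stride spatial subsampling factor of the output maps.
#' @param sigma Gaussian envelope SD in pixels; default `0.45 / frequency`.
#' @param orientation_offset rotation added to every orientation (radians);
#'   lets two banks cover complementary orientation sets.
#' @param id core identifier string.
#' @return An object of classes `gabor_core`, `feature_core` with
#'   `channels = orientations * length(frequencies) * length(phases)`.
#' @examples
#' core <- gabor_core(orientations = 4, frequencies = 0.15, phases = 0)
#' core$channels
#' @export
gabor_core <- function(orientations = 4, frequencies = c(0.1, 0.2),
                       phases = c(0, pi / 2), kernel_size = 11, stride = 3,
                       sigma = NULL, orientation_offset = 0,
                       id = "gabor_bank") {
  stopifnot(kernel_size %% 2 == 1, orientations >= 1)
  thetas <- orientation_offset +
    seq(0, pi, length.out = orientations + 1)[seq_len(orientations)]
  grid <- expand.grid(phase = phases, freq = frequencies, theta = thetas)
  half <- (kernel_size - 1) / 2
  xy <- -half:half
  xr <- outer(rep(1, kernel_size), xy)
  yr <- outer(xy, rep(1, kernel_size))
  filters <- array(0, c(kernel_size, kernel_size, nrow(grid)))
  for (k in seq_len(nrow(grid))) {
    th <- grid$theta[k]; f <- grid$freq[k]; ph <- grid$phase[k]
    s <- if (is.null(sigma)) 0.45 / f else sigma
    u <- xr * cos(th) + yr * sin(th)
    v <- -xr * sin(th) + yr * cos(th)
    g <- exp(-(u^2 + v^2) / (2 * s^2)) * cos(2 * pi * f * u + ph)
    g <- g - mean(g)                       # zero mean: constant input -> 0
    filters[, , k] <- g / sqrt(sum(g^2))   # unit norm
  }
  structure(
    list(
      id = id, layer_id = "bank", channels = as.integer(nrow(grid)),
      trained = TRUE,
      filters = filters, stride = as.integer(stride), params = grid
    ),
    class = c("gabor_core", "feature_core")
  )
}

#' Random convolutional network feature core
#'
#' A small seeded convolutional network (conv + rectify stages with spatial
#' striding) with frozen random weights: the analogue of the untrained
#' baseline used as a control for pretrained feature spaces. He-scaled
#' Gaussian weights, deterministic under `seed`.
#'
#' @param channels output channels per stage.
#' @param kernel_size odd kernel side length shared by all stages.
#' @param strides per-stage spatial stride.
#' @param seed integer seed for the weight draw.
#' @param id core identifier string.
#' @return An object of classes `random_convnet_core`, `feature_core`.
#' @export
random_convnet_core <- function(channels = c(8, 12, 16), kernel_size = 3,
                                strides = c(2, 2, 1), seed = 1,
                                id = "random_convnet") {
  stopifnot(kernel_size %% 2 == 1, length(strides) == length(channels))
  in_ch <- c(1L, channels[-length(channels)])
  weights <- with_seed(seed, {
    lapply(seq_along(channels), function(l) {
      fan_in <- kernel_size^2 * in_ch[l]
      array(stats::rnorm(kernel_size^2 * in_ch[l] * channels[l],
                         sd = sqrt(2 / fan_in)),
            c(kernel_size, kernel_size, in_ch[l], channels[l]))
    })
  })
  structure(
    list(
      id = id, layer_id = sprintf("stage%d", length(channels)),
      channels = as.integer(channels[length(channels)]), trained = FALSE,
      weights = weights, strides = as.integer(strides), seed = seed
    ),
    class = c("random_convnet_core", "feature_core")
  )
}

#' Wrap a user-supplied feature extractor as a core
#'
#' Adapter for external frozen cores: any function mapping an `n x H x W`
#' image array to an `n x h x w x channels` feature array can serve as a
#' core. Pretrained network weights are not bundled; supply your own forward
#' function.
#'
#' @param forward function `(images array) -> n x h x w x c feature array`.
#' @param channels declared number of output channels.
#' @param id,layer_id identifier strings.
#' @return An object of classes `custom_core`, `feature_core`.
#' @export
custom_core <- function(forward, channels, id = "custom", layer_id = "external") {
  stopifnot(is.function(forward), channels >= 1)
  structure(
    list(id = id, layer_id = layer_id, channels = as.integer(channels),
         trained = NA, forward = forward),
    class = c("custom_core", "feature_core")
  )
}

#' Concatenate feature cores along the channel axis
#'
#' Builds the joint feature space used by pair and triplet models: every
#' member core receives the identical preprocessed input, member feature maps
#' must share spatial dimensions, and outputs are concatenated channel-wise
#' with block boundaries recorded. Member parameters stay frozen.
#'
#' @param ... two or three `feature_core` objects.
#' @param id identifier; default joins member ids with `"+"`.
#' @return An object of classes `concat_core`, `feature_core` with a
#'   `blocks` list of per-member channel index ranges.
#' @export
concat_core <- function(..., id = NULL) {
  members <- list(...)
  if (length(members) == 1L && is.list(members[[1]]) &&
      !inherits(members[[1]], "feature_core")) {
    members <- members[[1]]
  }
  stopifnot(length(members) >= 2L, length(members) <= 3L)
  for (m in members) stopifnot(inherits(m, "feature_core"))
  ch <- vapply(members, function(m) m$channels, integer(1))
  ends <- cumsum(ch)
  starts <- c(1L, ends[-length(ends)] + 1L)
  blocks <- Map(function(s, e) s:e, starts, ends)
  if (is.null(id)) id <- paste(vapply(members, `[[`, "", "id"), collapse = "+")
  structure(
    list(id = id, layer_id = members[[1]]$layer_id, channels = sum(ch),
         trained = NA, members = members, blocks = blocks),
    class = c("concat_core", "feature_core")
  )
}

#' Compute raw feature maps of a frozen core
#'
#' Forwards images through a feature core, returning pre-normalization
#' feature maps. Deterministic: cores are frozen, so repeated calls with the
#' same input are bit-identical.
#'
#' @param core a `feature_core`.
#' @param images an `image_set`, matrix, or `n x H x W` array.
#' @return An `n x h x w x channels` array.
#' @export
core_features <- function(core, images) UseMethod("core_features")

#' @export
core_features.default <- function(core, images) {
  stop("unknown feature core of class ", paste(class(core), collapse = "/"))
}

#' @export
core_features.gabor_core <- function(core, images) {
  arr <- as_image_array(images)
  n <- dim(arr)[1]; h <- dim(arr)[2]; w <- dim(arr)[3]
  ri <- stride_index(h, core$stride)
  ci <- stride_index(w, core$stride)
  out <- array(0, c(n, length(ri), length(ci), core$channels))
  for (k in seq_len(core$channels)) {
    full <- conv2d_same(arr, core$filters[, , k])
    out[, , , k] <- full[, ri, ci, drop = FALSE]
  }
  out
}

#' @export
core_features.random_convnet_core <- function(core, images) {
  arr <- as_image_array(images)
  n <- dim(arr)[1]
  cur <- array(arr, c(dim(arr), 1L))        # n x h x w x 1
  for (l in seq_along(core$weights)) {
    wts <- core$weights[[l]]
    cin <- dim(wts)[3]; cout <- dim(wts)[4]
    h <- dim(cur)[2]; w <- dim(cur)[3]
    nxt <- array(0, c(n, h, w, cout))
    for (co in seq_len(cout)) {
      acc <- array(0, c(n, h, w))
      for (ci in seq_len(cin)) {
        acc <- acc + conv2d_same(cur[, , , ci, drop = TRUE] |>
                                   array(c(n, h, w)), wts[, , ci, co])
      }
      nxt[, , , co] <- acc
    }
    nxt <- pmax(nxt, 0)                     # rectify each stage
    s <- core$strides[l]
    if (s > 1L) {
      nxt <- nxt[, stride_index(h, s), stride_index(w, s), , drop = FALSE]
    }
    cur <- nxt
  }
  cur
}

#' @export
core_features.custom_core <- function(core, images) {
  arr <- as_image_array(images)
  out <- core$forward(arr)
  stopifnot(length(dim(out)) == 4L, dim(out)[4] == core$channels)
  out
}

#' @export
core_features.concat_core <- function(core, images) {
  arr <- as_image_array(images)
  feats <- lapply(core$members, core_features, images = arr)
  sp <- dim(feats[[1]])[2:3]
  for (f in feats) {
    if (!all(dim(f)[2:3] == sp)) {
      stop("member cores produce mismatched spatial dimensions; ",
           "all members must share the same input scale and map size")
    }
  }
  # channel is the slowest-varying dimension, so channel-wise concatenation
  # is plain vector concatenation
  array(unlist(feats, use.names = FALSE),
        c(dim(feats[[1]])[1:3], core$channels))
}

#' @export
print.feature_core <- function(x, ...) {
  cat(sprintf("<feature_core:%s> id=%s layer=%s channels=%d\n",
              class(x)[1], x$id, x$layer_id, x$channels))
  invisible(x)
}
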