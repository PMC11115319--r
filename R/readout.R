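# Gaussian point readout: each neuron reads the feature tensor at a single
# continuous spatial location in relative coordinates ([-1, 1]^2, map center
# at (0, 0)), takes a linear combination across channels, adds a bias, and
# passes the result through ELU + 1 so predicted rates are strictly
# positive. During training the location is sampled from an isotropic
# Gaussian N(mu_n, sigma_n^2 I) via the reparameterization trick; at
# evaluation the readout is deterministic and uses mu_n.

#' Initialize per-neuron readout parameters
#'
#' Positions start at the map center plus a small jitter; the position SD is
#' initialized to cover about 25% of the map width so gradients reach the
#' whole map early in training; feature weights start near zero. The
#' isotropic variance is carried through a softplus parameterization
#' (`sigma2 = softplus(rho)`) to stay nonnegative. Each neuron has
#' `channels + 4` parameters: channel weights, bivariate position mean,
#' position variance, and bias.
#'
#' @param n_neurons number of neurons.
#' @param channels feature channels.
#' @param init_sd initial position-sampling SD in relative units.
#' @param jitter SD of the initial position jitter.
#' @param weight_sd SD of the initial weight draw.
#' @param seed integer seed.
#' @return A list with `mu` (`n x 2`), `rho` (`n`), `weights` (`n x channels`),
#'   `bias` (`n`).
#' @export
readout_init <- function(n_neurons, channels, init_sd = 0.5, jitter = 0.05,
                         weight_sd = 0.01, seed = 1) {
  with_seed(seed, {
    list(
      mu = matrix(stats::rnorm(2 * n_neurons, 0, jitter), n_neurons, 2),
      rho = rep(inv_softplus(init_sd^2), n_neurons),
      weights = matrix(stats::rnorm(n_neurons * channels, 0, weight_sd),
                       n_neurons, channels),
      bias = rep(0, n_neurons)
    )
  })
}

#' Sample readout positions
#'
#' Train mode draws reparameterized positions `mu + sqrt(sigma2) * eps` with
#' `eps ~ N(0, I)` (so gradients flow to both `mu` and `sigma2`), clamped to
#' the valid domain \[-1, 1\]^2; eval mode returns `mu` exactly.
#'
#' @param mu `n x 2` matrix of position means (relative coordinates).
#' @param sigma2 length-`n` nonnegative isotropic position variances.
#' @param mode `"eval"` or `"train"`.
#' @param eps optional `n x 2` matrix of standard-normal draws (supplied for
#'   reproducibility; drawn internally otherwise).
#' @return A list with `pos` (`n x 2`, clamped), `raw` (pre-clamp positions)
#'   and `eps`.
#' @export
sample_position <- function(mu, sigma2, mode = c("eval", "train"), eps = NULL) {
  mode <- match.arg(mode)
  mu <- rbind(mu)
  stopifnot(ncol(mu) == 2, all(sigma2 >= 0))
  if (mode == "eval") {
    pos <- clamp(mu, -1, 1)
    return(list(pos = pos, raw = mu, eps = matrix(0, nrow(mu), 2)))
  }
  if (is.null(eps)) eps <- matrix(stats::rnorm(2 * nrow(mu)), nrow(mu), 2)
  raw <- mu + sqrt(sigma2) * eps
  list(pos = clamp(raw, -1, 1), raw = raw, eps = eps)
}

# Bilinear interpolation bookkeeping for one location on an H x W grid in
# relative coordinates with align-corners convention: pixel j of W sits at
# x = -1 + 2 (j - 1) / (W - 1). Returns corner indices, the four corner
# weights, and the derivatives of the interpolated value with respect to the
# relative coordinates.
interp_info <- function(h, w, x, y) {
  stopifnot(h >= 2, w >= 2)
  gx <- (clamp(x, -1, 1) + 1) * (w - 1) / 2 + 1
  gy <- (clamp(y, -1, 1) + 1) * (h - 1) / 2 + 1
  ix0 <- pmin(floor(gx), w - 1); tx <- gx - ix0
  iy0 <- pmin(floor(gy), h - 1); ty <- gy - iy0
  list(
    ix0 = as.integer(ix0), ix1 = as.integer(ix0 + 1),
    iy0 = as.integer(iy0), iy1 = as.integer(iy0 + 1),
    tx = tx, ty = ty,
    w00 = (1 - ty) * (1 - tx), w01 = (1 - ty) * tx,
    w10 = ty * (1 - tx), w11 = ty * tx,
    dx_scale = (w - 1) / 2, dy_scale = (h - 1) / 2
  )
}

# Extract one spatial corner of a batch feature tensor as an n x c matrix.
corner_mat <- function(phi, iy, ix) {
  d <- dim(phi)
  matrix(phi[, iy, ix, , drop = FALSE], d[1], d[4])
}

# Interpolate a batch feature tensor (n x h x w x c) at one location.
# Returns an n x c matrix.
interp_features <- function(phi, info) {
  corner_mat(phi, info$iy0, info$ix0) * info$w00 +
    corner_mat(phi, info$iy0, info$ix1) * info$w01 +
    corner_mat(phi, info$iy1, info$ix0) * info$w10 +
    corner_mat(phi, info$iy1, info$ix1) * info$w11
}

#' Evaluate point readouts on a feature tensor
#'
#' Interpolates the rectified feature tensor bilinearly at each neuron's
#' location, forms the weighted channel sum plus bias, and applies ELU + 1.
#' Output is strictly positive for all finite inputs, and depends only on
#' feature values inside the 2 x 2 interpolation neighborhood of each
#' location.
#'
#' @param features an `h x w x c` array (single image) or `n x h x w x c`
#'   batch.
#' @param weights `n_neurons x c` matrix (or length-`c` vector).
#' @param bias length-`n_neurons` vector (or scalar).
#' @param location `n_neurons x 2` matrix of relative coordinates (or a
#'   length-2 vector), columns `(x, y)`.
#' @return An `n_images x n_neurons` matrix of predicted rates.
#' @export
readout_forward <- function(features, weights, bias, location) {
  if (length(dim(features)) == 3L) {
    features <- array(features, c(1L, dim(features)))
  }
  stopifnot(length(dim(features)) == 4L)
  weights <- rbind(weights)
  location <- rbind(location)
  n_neurons <- nrow(weights)
  bias <- rep_len(bias, n_neurons)
  d <- dim(features)
  if (ncol(weights) != d[4]) {
    stop(sprintf("weight length %d does not match %d feature channels",
                 ncol(weights), d[4]))
  }
  stopifnot(nrow(location) == n_neurons, ncol(location) == 2)
  if (any(abs(location) > 1)) stop("locations must lie in [-1, 1]^2")
  out <- matrix(0, d[1], n_neurons)
  for (n in seq_len(n_neurons)) {
    info <- interp_info(d[2], d[3], location[n, 1], location[n, 2])
    phi_n <- interp_features(features, info)
    eta <- drop(phi_n %*% weights[n, ]) + bias[n]
    out[, n] <- elu1(eta)
  }
  out
}
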