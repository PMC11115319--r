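# Shared feature head: per-channel batch normalization with trainable scale
# (gamma) and shift (beta), followed by rectification. Normalizing each
# channel to zero mean / unit variance before rectification lets a single L1
# penalty act comparably on all readout weights.

#' Create a batch-normalizing feature head
#'
#' Holds per-channel scale `gamma`, shift `beta` and running mean/variance.
#' In train mode the forward pass normalizes with batch statistics and blends
#' the running statistics with momentum; in eval mode it is a deterministic
#' affine transform using the stored running statistics, followed by
#' rectification.
#'
#' @param channels number of feature channels.
#' @param momentum running-statistics blending factor in (0, 1\].
#' @param eps variance floor added inside the square root.
#' @return An object of class `feature_head`.
#' @export
feature_head <- function(channels, momentum = 0.1, eps = 1e-5) {
  stopifnot(channels >= 1, momentum > 0, momentum <= 1)
  structure(
    list(
      gamma = rep(1, channels), beta = rep(0, channels),
      running_mean = rep(0, channels), running_var = rep(1, channels),
      momentum = momentum, eps = eps, channels = as.integer(channels)
    ),
    class = "feature_head"
  )
}

#' Apply the feature head to raw core features
#'
#' `BN(x) = gamma * (x - mu) / sigma + beta` per channel, then elementwise
#' rectification `max(., 0)`. Train mode uses batch statistics over all
#' images and spatial positions of each channel and updates the running
#' statistics (exponential blending; the running variance uses the unbiased
#' batch estimate); eval mode uses the stored running statistics and mutates
#' nothing.
#'
#' @param raw `n x h x w x channels` array of raw core features.
#' @param head a [feature_head()].
#' @param mode `"eval"` or `"train"`.
#' @return A list with `phi` (the rectified feature tensor, same shape as
#'   `raw`), `pre` (pre-rectification values) and `head` (the head, updated
#'   in train mode).
#' @export
feature_head_forward <- function(raw, head, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  stopifnot(inherits(head, "feature_head"))
  d <- dim(raw)
  stopifnot(length(d) == 4L, d[4] == head$channels)
  M <- matrix(raw, ncol = d[4])
  nr <- nrow(M)
  if (mode == "train") {
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2
    v <- pmax(v, 0)
    m <- head$momentum
    head$running_mean <- (1 - m) * head$running_mean + m * mu
    vu <- if (nr > 1) v * nr / (nr - 1) else v
    head$running_var <- (1 - m) * head$running_var + m * vu
  } else {
    mu <- head$running_mean
    v <- head$running_var
  }
  sd_ <- sqrt(v + head$eps)
  if (any(sd_ <= 0)) stop("feature head has non-positive channel scale")
  xhat <- (M - rep(mu, each = nr)) / rep(sd_, each = nr)
  pre <- xhat * rep(head$gamma, each = nr) + rep(head$beta, each = nr)
  list(
    phi = array(pmax(pre, 0), d),
    pre = array(pre, d),
    xhat = array(xhat, d),
    head = head
  )
}
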