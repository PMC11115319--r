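# Training objective: summed Poisson loss across neurons and batch elements
# plus an L1 penalty on readout feature weights, and its analytic gradient
# with respect to every trainable parameter (feature-head gamma/beta and
# per-neuron position mean, position variance, weights, bias).

#' Poisson + L1 training objective
#'
#' `sum(rate - counts * log(rate))` over neurons and batch elements, plus
#' `lambda * sum(abs(weights))`. Predicted rates must be positive; a small
#' `eps` guards the logarithm against underflow of the ELU + 1 output. The
#' bias is not penalized.
#'
#' @param rate matrix (or vector) of predicted rates, > 0.
#' @param counts observed spike counts, nonnegative integers, same shape.
#' @param weights optional readout weight matrix entering the L1 penalty.
#' @param lambda L1 penalty strength.
#' @param eps numerical guard inside the logarithm.
#' @return Scalar loss.
#' @examples
#' poisson_l1_loss(1, 1)                        # 1 - 1 * log(1) = 1
#' poisson_l1_loss(1, 0)                        # 1
#' poisson_l1_loss(1, 1, weights = c(1, -2), lambda = 3)  # 1 + 9
#' @export
poisson_l1_loss <- function(rate, counts, weights = NULL, lambda = 0,
                            eps = 1e-8) {
  if (any(rate <= 0)) stop("predicted rates must be positive")
  if (any(counts < 0)) stop("counts must be nonnegative")
  loss <- sum(rate - counts * log(rate + eps))
  if (!is.null(weights) && lambda != 0) {
    loss <- loss + lambda * sum(abs(weights))
  }
  loss
}

# Zero-filled gradient container matching the trainable parameter list.
zero_grads <- function(params) {
  list(
    gamma = numeric(length(params$gamma)),
    beta = numeric(length(params$beta)),
    mu = matrix(0, nrow(params$mu), 2),
    rho = numeric(length(params$rho)),
    weights = matrix(0, nrow(params$weights), ncol(params$weights)),
    bias = numeric(length(params$bias))
  )
}

add_grads <- function(a, b) Map(`+`, a, b)

scale_params <- function(params, mask) {
  if (is.null(mask)) return(params)
  Map(`*`, params, mask)
}

# Gather phi values at per-image integer corner positions: returns a B x C
# matrix where row i is phi[i, iy[i], ix[i], ].
gather_corner <- function(phi, iy, ix) {
  d <- dim(phi)
  B <- d[1]
  base <- seq_len(B) + B * (iy - 1L) + B * d[2] * (ix - 1L)
  lin <- outer(base, B * d[2] * d[3] * (seq_len(d[4]) - 1L), "+")
  matrix(phi[as.vector(lin)], B, d[4])
}

# Loss and analytic gradient for one session batch.
#
# params: list(gamma, beta, mu [N x 2], rho [N], weights [N x C], bias [N])
#   over the *global* neuron set; nidx gives this session's global indices.
# Z: B x h x w x C raw core features for the batch.
# counts: B x length(nidx) observed spike counts.
# head_state: list(running_mean, running_var, momentum, eps).
# eps_draws: standard-normal draws for position sampling in train mode --
#   a B x 2 x length(nidx) array (one location per image and neuron) or a
#   length(nidx) x 2 matrix (one location per neuron, shared by the batch);
#   ignored in eval mode.
# Returns list(loss, grads, head_state).
session_gradient <- function(params, Z, counts, nidx, lambda, head_state,
                             mode = c("train", "eval"), eps_draws = NULL,
                             update_running = TRUE, log_eps = 1e-8) {
  mode <- match.arg(mode)
  d <- dim(Z)
  B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  M <- matrix(Z, ncol = C)
  nr <- nrow(M)

  if (mode == "train") {
    bmu <- colMeans(M)
    bvar <- pmax(colMeans(M^2) - bmu^2, 0)
    if (update_running) {
      m <- head_state$momentum
      head_state$running_mean <- (1 - m) * head_state$running_mean + m * bmu
      vu <- if (nr > 1) bvar * nr / (nr - 1) else bvar
      head_state$running_var <- (1 - m) * head_state$running_var + m * vu
    }
  } else {
    bmu <- head_state$running_mean
    bvar <- head_state$running_var
  }
  sd_ <- sqrt(bvar + head_state$eps)
  xhat <- (M - rep(bmu, each = nr)) / rep(sd_, each = nr)
  pre <- xhat * rep(params$gamma, each = nr) + rep(params$beta, each = nr)
  active <- pre > 0
  phi <- array(pre * active, d)
  xhat <- array(xhat, d)
  active <- array(active, d)

  grads <- zero_grads(params)
  loss <- 0
  if (is.null(eps_draws)) eps_draws <- array(0, c(B, 2, length(nidx)))
  if (is.matrix(eps_draws)) {
    # one draw per neuron, shared across the batch
    em <- eps_draws
    eps_draws <- array(0, c(B, 2, nrow(em)))
    for (dd in 1:2) eps_draws[, dd, ] <- matrix(em[, dd], B, nrow(em),
                                                byrow = TRUE)
  }

  sigma2 <- softplus(params$rho)
  sdpos <- sqrt(sigma2)

  for (j in seq_along(nidx)) {
    n <- nidx[j]
    w_n <- params$weights[n, ]
    if (mode == "train") {
      ex <- eps_draws[, 1, j]; ey <- eps_draws[, 2, j]
      raw_x <- params$mu[n, 1] + sdpos[n] * ex
      raw_y <- params$mu[n, 2] + sdpos[n] * ey
    } else {
      ex <- ey <- numeric(B)
      raw_x <- rep(params$mu[n, 1], B)
      raw_y <- rep(params$mu[n, 2], B)
    }
    info <- interp_info(H, W, raw_x, raw_y)   # clamps internally, vectorized

    P00 <- gather_corner(phi, info$iy0, info$ix0)
    P01 <- gather_corner(phi, info$iy0, info$ix1)
    P10 <- gather_corner(phi, info$iy1, info$ix0)
    P11 <- gather_corner(phi, info$iy1, info$ix1)
    phi_n <- P00 * info$w00 + P01 * info$w01 + P10 * info$w10 + P11 * info$w11

    eta <- drop(phi_n %*% w_n) + params$bias[n]
    rate <- elu1(eta)
    r <- counts[, j]
    loss <- loss + sum(rate - r * log(rate + log_eps)) + lambda * sum(abs(w_n))

    g <- (1 - r / (rate + log_eps)) * elu1_prime(eta)   # dL/deta, length B
    grads$bias[n] <- grads$bias[n] + sum(g)
    grads$weights[n, ] <- grads$weights[n, ] + drop(crossprod(phi_n, g)) +
      lambda * sign(w_n)

    # feature-head gradients through the four corners
    for (cc in list(
      list(a = info$w00, iy = info$iy0, ix = info$ix0),
      list(a = info$w01, iy = info$iy0, ix = info$ix1),
      list(a = info$w10, iy = info$iy1, ix = info$ix0),
      list(a = info$w11, iy = info$iy1, ix = info$ix1)
    )) {
      dU <- outer(cc$a * g, w_n) * gather_corner(active, cc$iy, cc$ix)
      grads$gamma <- grads$gamma +
        colSums(dU * gather_corner(xhat, cc$iy, cc$ix))
      grads$beta <- grads$beta + colSums(dU)
    }

    # position gradients, per image (zero on axes where the sampled
    # position clamped outside the map)
    dphi_dx <- ((1 - info$ty) * (P01 - P00) + info$ty * (P11 - P10)) *
      info$dx_scale
    dphi_dy <- ((1 - info$tx) * (P10 - P00) + info$tx * (P11 - P01)) *
      info$dy_scale
    dLdx_i <- g * drop(dphi_dx %*% w_n) * (abs(raw_x) <= 1)
    dLdy_i <- g * drop(dphi_dy %*% w_n) * (abs(raw_y) <= 1)
    grads$mu[n, ] <- grads$mu[n, ] + c(sum(dLdx_i), sum(dLdy_i))
    if (mode == "train" && sdpos[n] > 0) {
      dsd_drho <- sigmoid(params$rho[n]) / (2 * sdpos[n])
      grads$rho[n] <- grads$rho[n] +
        sum(dLdx_i * ex + dLdy_i * ey) * dsd_drho
    }
  }

  list(loss = loss, grads = grads, head_state = head_state)
}

# Eval-mode Poisson loss of a session (no L1), plus per-image predicted
# rates. Used for validation passes and prediction.
session_eval <- function(params, Fmat, counts, nidx, head_state,
                         log_eps = 1e-8, rates_only = FALSE) {
  d <- dim(Fmat)
  nr <- prod(d[1:3])
  M <- matrix(Fmat, ncol = d[4])
  sd_ <- sqrt(head_state$running_var + head_state$eps)
  xhat <- (M - rep(head_state$running_mean, each = nr)) / rep(sd_, each = nr)
  pre <- xhat * rep(params$gamma, each = nr) + rep(params$beta, each = nr)
  phi <- array(pmax(pre, 0), d)
  rates <- matrix(0, d[1], length(nidx))
  for (j in seq_along(nidx)) {
    n <- nidx[j]
    pos <- clamp(params$mu[n, ], -1, 1)
    info <- interp_info(d[2], d[3], pos[1], pos[2])
    phi_n <- interp_features(phi, info)
    rates[, j] <- elu1(drop(phi_n %*% params$weights[n, ]) + params$bias[n])
  }
  if (rates_only) return(rates)
  list(loss = sum(rates - counts * log(rates + log_eps)), n = d[1],
       rates = rates)
}
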