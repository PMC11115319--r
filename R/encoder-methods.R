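# Methods for fitted spike_encoder objects.

#' @export
print.spike_encoder <- function(x, ...) {
  h <- x$history
  cat(sprintf("<spike_encoder> core %s (%d channels, %dx%d map), %d neurons\n",
              x$core$id, x$channels, x$map_dim[1], x$map_dim[2],
              nrow(x$neurons)))
  cat(sprintf("  lambda %.3g, %d epochs, best validation loss %.5f (epoch %d)\n",
              x$lambda, max(h$epoch), min(h$val_loss),
              attr(h, "best_epoch")))
  if (!is.null(x$strategy)) cat(sprintf("  strategy: %s\n", x$strategy))
  invisible(x)
}

#' Extract readout coefficients
#'
#' @param object a fitted `spike_encoder`.
#' @param ... unused.
#' @return A list with `mu` (`n x 2` position means), `sigma2` (isotropic
#'   position variances), `weights` (`n x channels`), `bias`, and the
#'   feature-head `gamma`/`beta`.
#' @export
coef.spike_encoder <- function(object, ...) {
  p <- object$params
  list(mu = p$mu, sigma2 = softplus(p$rho), weights = p$weights,
       bias = p$bias, gamma = p$gamma, beta = p$beta)
}

#' Predict firing rates for new images
#'
#' Deterministic evaluation-mode forward pass: frozen core, feature head
#' with stored running statistics, readout at each neuron's position mean.
#'
#' @param object a fitted `spike_encoder`.
#' @param newdata an `image_set`, image matrix/array, or an `area_dataset`
#'   (in which case the shared test images are used).
#' @param ... unused.
#' @return An `n_images x n_neurons` matrix of predicted rates.
#' @export
predict.spike_encoder <- function(object, newdata, ...) {
  imgs <- if (inherits(newdata, "area_dataset")) newdata$test_images else newdata
  Fmat <- core_features(object$core, imgs)
  session_eval(object$params, Fmat, NULL, object$neurons$global,
               object$head_state, rates_only = TRUE)
}

#' Simulate Poisson spike counts from a fitted model
#'
#' @param object a fitted `spike_encoder`.
#' @param nsim repeats per image.
#' @param seed integer seed.
#' @param newdata images (required).
#' @param ... unused.
#' @return An `n_images x nsim x n_neurons` array of Poisson counts.
#' @export
simulate.spike_encoder <- function(object, nsim = 1, seed = 1, newdata, ...) {
  rates <- predict(object, newdata)
  with_seed(seed, {
    out <- array(0L, c(nrow(rates), nsim, ncol(rates)))
    for (t in seq_len(nsim)) {
      out[, t, ] <- stats::rpois(length(rates), rates)
    }
    out
  })
}

#' Residuals of a fitted encoding model on repeated-trial data
#'
#' Compares predictions with repeat-averaged test responses.
#'
#' @param object a fitted `spike_encoder`.
#' @param dataset an `area_dataset` with test counts.
#' @param type `"response"` (mean response minus prediction) or `"pearson"`
#'   (scaled by `sqrt(rate)`, the Poisson standard deviation).
#' @param ... unused.
#' @return An `n_images x n_neurons` matrix.
#' @export
residuals.spike_encoder <- function(object, dataset,
                                    type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(dataset, "area_dataset"))
  pred <- predict(object, dataset)
  obs <- dataset_test_counts(dataset)
  mean_resp <- apply(obs, c(1, 3), mean)
  res <- mean_resp - pred
  if (type == "pearson") res <- res / sqrt(pred)
  res
}

#' Summarize a fitted encoding model
#'
#' Reports the fit history and, when a dataset with repeated-trial test
#' responses is supplied, per-neuron reliability and performance.
#'
#' @param object a fitted `spike_encoder`.
#' @param dataset optional `area_dataset` for test-set performance.
#' @param ... unused.
#' @return An object of class `summary.spike_encoder`.
#' @export
summary.spike_encoder <- function(object, dataset = NULL, ...) {
  out <- list(
    model = object,
    n_neurons = nrow(object$neurons),
    best_val = min(object$history$val_loss),
    epochs = max(object$history$epoch),
    decay_epochs = attr(object$history, "decay_epochs"),
    score = NULL
  )
  if (!is.null(dataset)) out$score <- evaluate(object, dataset)
  structure(out, class = "summary.spike_encoder")
}

#' @export
print.summary.spike_encoder <- function(x, ...) {
  print(x$model)
  cat(sprintf("  learning-rate decays at epochs: %s\n",
              paste(x$decay_epochs, collapse = ", ")))
  if (!is.null(x$score)) {
    print(x$score)
  }
  invisible(x)
}

#' Plot a fitted encoding model
#'
#' `which = 1`: readout position means in relative coordinates, circle
#' radius showing the position-sampling SD. `which = 2`: training and
#' validation loss history with decay events marked.
#'
#' @param x a fitted `spike_encoder`.
#' @param which which panels to draw.
#' @param ... passed to plotting functions.
#' @export
plot.spike_encoder <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  cf <- coef(x)
  if (1 %in% which) {
    graphics::plot(cf$mu[, 1], cf$mu[, 2], xlim = c(-1, 1), ylim = c(-1, 1),
                   xlab = "x (relative)", ylab = "y (relative)",
                   main = "readout positions", pch = 19, cex = 0.6, ...)
    graphics::symbols(cf$mu[, 1], cf$mu[, 2], circles = sqrt(cf$sigma2),
                      inches = FALSE, add = TRUE, fg = "grey70")
    graphics::abline(h = 0, v = 0, lty = 3, col = "grey80")
  }
  if (2 %in% which) {
    h <- x$history
    graphics::plot(h$epoch, h$val_loss, type = "l", xlab = "epoch",
                   ylab = "loss", main = "fit history", ...)
    graphics::lines(h$epoch, h$train_loss, lty = 2, col = "grey50")
    graphics::abline(v = attr(h, "decay_epochs"), lty = 3, col = "red3")
    graphics::legend("topright", c("validation", "train"), lty = c(1, 2),
                     col = c("black", "grey50"), bty = "n")
  }
  invisible(x)
}
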