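# Synthetic ground truth: populations of model neurons whose firing rates
# are a known point-readout function of frozen core features, observed
# through Poisson spiking. Every downstream stage (fitting, reliability
# estimation, model comparison) is testable against this ground truth by
# parameter recovery.

#' Generate a ground-truth neuron population
#'
#' Neurons read a frozen core's feature maps (per-channel standardized and
#' rectified) at a random position uniform in \[-1, 1\]^2, with sparse
#' zero-mean Gaussian channel weights, a bias, and an ELU + 1 output
#' nonlinearity scaled by a positive gain. The generated rate is strictly
#' positive for every input. Weight scale is `1 / sqrt(channels * sparsity)`
#' so that, with the default gain, median spike counts fall in the 0-10
#' range typical of cortical responses in a brief counting window.
#'
#' @param core a `feature_core` generating the neurons' input features.
#' @param n_neurons number of neurons.
#' @param weight_sparsity expected fraction of nonzero weights, in (0, 1\].
#' @param gain positive rate scale.
#' @param bias_sd SD of the bias draw.
#' @param seed integer seed.
#' @return An object of class `gt_population` with matrices `positions`
#'   (`n x 2`), `weights` (`n x channels`), vectors `bias` and `gain`, the
#'   core, and (initially unset) per-channel standardization statistics.
#' @export
make_population <- function(core, n_neurons, weight_sparsity = 0.3, gain = 6,
                            bias_sd = 0.2, seed = 1) {
  stopifnot(inherits(core, "feature_core"), n_neurons >= 1,
            weight_sparsity > 0, weight_sparsity <= 1, gain > 0)
  C <- core$channels
  out <- with_seed(seed, {
    mask <- matrix(stats::runif(n_neurons * C) < weight_sparsity, n_neurons, C)
    # guarantee at least one active channel per neuron
    for (i in which(rowSums(mask) == 0)) mask[i, sample.int(C, 1)] <- TRUE
    wsd <- 1 / sqrt(C * weight_sparsity)
    list(
      positions = matrix(stats::runif(2 * n_neurons, -1, 1), n_neurons, 2),
      weights = matrix(stats::rnorm(n_neurons * C, 0, wsd), n_neurons, C) * mask,
      bias = stats::rnorm(n_neurons, 0, bias_sd),
      gain = rep(gain, n_neurons)
    )
  })
  structure(
    c(out, list(core = core, layer_id = core$layer_id, n_neurons = n_neurons,
                channels = C, weight_sparsity = weight_sparsity,
                norm_stats = NULL, seed = seed)),
    class = "gt_population"
  )
}

#' @export
print.gt_population <- function(x, ...) {
  cat(sprintf("<gt_population> %d neurons on core %s (%d channels), sparsity %.2g\n",
              x$n_neurons, x$core$id, x$channels, x$weight_sparsity))
  invisible(x)
}

# Fix the per-channel standardization statistics of the generative feature
# space from a reference image set (typically the training pool), so the
# same deterministic rate function applies to every later image set.
calibrate_population <- function(pop, images) {
  Fmat <- core_features(pop$core, images)
  M <- matrix(Fmat, ncol = dim(Fmat)[4])
  pop$norm_stats <- list(mean = colMeans(M), sd = pmax(apply(M, 2, stats::sd), 1e-8))
  pop
}

#' Ground-truth firing rates of a population
#'
#' Deterministic rate function: standardized rectified core features,
#' bilinear interpolation at each neuron's position, weighted channel sum
#' plus bias, ELU + 1, times gain.
#'
#' @param pop a `gt_population` (calibrated; otherwise statistics are taken
#'   from `images`).
#' @param images an `image_set`, matrix or `n x H x W` array.
#' @return An `n_images x n_neurons` matrix of positive rates.
#' @export
true_rates <- function(pop, images) {
  stopifnot(inherits(pop, "gt_population"))
  Fmat <- core_features(pop$core, images)
  d <- dim(Fmat)
  if (is.null(pop$norm_stats)) pop <- calibrate_population_from(pop, Fmat)
  nr <- prod(d[1:3])
  M <- matrix(Fmat, ncol = d[4])
  M <- (M - rep(pop$norm_stats$mean, each = nr)) /
    rep(pop$norm_stats$sd, each = nr)
  phi <- array(pmax(M, 0), d)
  rates <- matrix(0, d[1], pop$n_neurons)
  for (n in seq_len(pop$n_neurons)) {
    info <- interp_info(d[2], d[3], pop$positions[n, 1], pop$positions[n, 2])
    phi_n <- interp_features(phi, info)
    rates[, n] <- pop$gain[n] *
      elu1(drop(phi_n %*% pop$weights[n, ]) + pop$bias[n])
  }
  rates
}

calibrate_population_from <- function(pop, Fmat) {
  M <- matrix(Fmat, ncol = dim(Fmat)[4])
  pop$norm_stats <- list(mean = colMeans(M), sd = pmax(apply(M, 2, stats::sd), 1e-8))
  pop
}

#' Simulate Poisson spike counts from a ground-truth population
#'
#' Counts are drawn independently as `Poisson(rate)` per image, repeat and
#' neuron.
#'
#' @param pop a `gt_population`.
#' @param images images compatible with the population's core.
#' @param repeats number of repeated presentations per image (>= 1).
#' @param seed integer seed.
#' @return An `n_images x repeats x n_neurons` integer array (the repeat
#'   axis is kept even for `repeats = 1`).
#' @export
simulate_responses <- function(pop, images, repeats = 1, seed = 1) {
  stopifnot(repeats >= 1)
  rates <- true_rates(pop, images)
  with_seed(seed, {
    out <- array(0L, c(nrow(rates), repeats, ncol(rates)))
    for (t in seq_len(repeats)) {
      out[, t, ] <- stats::rpois(length(rates), rates)
    }
    out
  })
}

#' Assemble a multi-session synthetic dataset for one area
#'
#' Emulates the structure of multi-session physiology datasets: each session
#' draws its own disjoint train/validation images (sessions see different
#' images), while a single shared test set is presented with many repeats.
#' By default 75 test images with 45 repeats and a 20% validation split.
#' Session neurons are disjoint subsets of one ground-truth population.
#'
#' @param n_sessions number of sessions.
#' @param images_per_session unique single-trial images per session (split
#'   into train and validation).
#' @param n_test_images shared repeated-trial test images (>= 2).
#' @param test_repeats repeats per test image.
#' @param validation_fraction fraction of each session's images held out for
#'   validation, in (0, 1).
#' @param neurons_per_session neurons recorded in each session.
#' @param core feature core generating the ground truth; default a Gabor
#'   bank.
#' @param image_size stimulus side length in pixels.
#' @param gain,weight_sparsity passed to [make_population()].
#' @param seed integer seed; the full dataset is reproducible from it.
#' @return An object of class `area_dataset`: a list with `sessions` (each
#'   holding `train_images`, `train_counts`, `validation_images`,
#'   `validation_counts`, `test_counts`, `neuron_ids`), the shared
#'   `test_images`, the generating `population`, and the generator
#'   parameters.
#' @export
assemble_area_dataset <- function(n_sessions = 2, images_per_session = 1000,
                                  n_test_images = 75, test_repeats = 45,
                                  validation_fraction = 0.2,
                                  neurons_per_session = 20, core = NULL,
                                  image_size = 40, gain = 6,
                                  weight_sparsity = 0.3, seed = 1) {
  stopifnot(n_test_images >= 2, validation_fraction > 0,
            validation_fraction < 1, n_sessions >= 1)
  if (is.null(core)) core <- gabor_core()
  n_pool <- n_sessions * images_per_session + n_test_images
  imgs <- sim_images(n_pool, size = image_size, seed = seed)$images

  test_images <- imgs[seq_len(n_test_images), , , drop = FALSE]

  N <- n_sessions * neurons_per_session
  pop <- make_population(core, N, weight_sparsity = weight_sparsity,
                         gain = gain, seed = seed + 1L)
  # standardization statistics fixed from (a sample of) the train pool
  pool_idx <- (n_test_images + 1L):n_pool
  calib_idx <- pool_idx[seq_len(min(500L, length(pool_idx)))]
  pop <- calibrate_population(pop, imgs[calib_idx, , , drop = FALSE])

  n_val <- round(validation_fraction * images_per_session)
  n_trn <- images_per_session - n_val

  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    s_imgs <- imgs[n_test_images + (s - 1L) * images_per_session +
                     seq_len(images_per_session), , , drop = FALSE]
    split <- with_seed(seed + 100L + s, sample.int(images_per_session))
    tr <- s_imgs[split[seq_len(n_trn)], , , drop = FALSE]
    va <- s_imgs[split[(n_trn + 1L):images_per_session], , , drop = FALSE]
    nid <- (s - 1L) * neurons_per_session + seq_len(neurons_per_session)
    spop <- subset_population(pop, nid)
    tc <- simulate_responses(spop, tr, repeats = 1, seed = seed + 200L + s)
    vc <- simulate_responses(spop, va, repeats = 1, seed = seed + 300L + s)
    xc <- simulate_responses(spop, test_images, repeats = test_repeats,
                             seed = seed + 400L + s)
    sessions[[s]] <- list(
      session_id = sprintf("S%02d", s),
      train_images = tr,
      train_counts = matrix(tc[, 1, ], dim(tr)[1], length(nid)),
      validation_images = va,
      validation_counts = matrix(vc[, 1, ], dim(va)[1], length(nid)),
      test_counts = xc,
      neuron_ids = nid
    )
  }

  structure(
    list(sessions = sessions, test_images = test_images, population = pop,
         params = list(n_sessions = n_sessions,
                       images_per_session = images_per_session,
                       n_test_images = n_test_images,
                       test_repeats = test_repeats,
                       validation_fraction = validation_fraction,
                       neurons_per_session = neurons_per_session,
                       image_size = image_size, gain = gain,
                       weight_sparsity = weight_sparsity, seed = seed)),
    class = "area_dataset"
  )
}

subset_population <- function(pop, idx) {
  pop$positions <- pop$positions[idx, , drop = FALSE]
  pop$weights <- pop$weights[idx, , drop = FALSE]
  pop$bias <- pop$bias[idx]
  pop$gain <- pop$gain[idx]
  pop$n_neurons <- length(idx)
  pop
}

#' @export
print.area_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<area_dataset> %d sessions x %d images (%d%% validation), %d neurons/session\n",
    p$n_sessions, p$images_per_session, round(100 * p$validation_fraction),
    p$neurons_per_session
  ))
  cat(sprintf("  shared test set: %d images x %d repeats; %dx%d px; seed %d\n",
              p$n_test_images, p$test_repeats, p$image_size, p$image_size,
              p$seed))
  invisible(x)
}

# Concatenate per-session test counts along the neuron axis:
# images x repeats x total neurons.
dataset_test_counts <- function(dataset) {
  xs <- lapply(dataset$sessions, `[[`, "test_counts")
  d1 <- dim(xs[[1]])
  array(unlist(xs, use.names = FALSE),
        c(d1[1], d1[2], sum(vapply(xs, function(x) dim(x)[3], integer(1)))))
}

#' Save or load a dataset or fitted model
#'
#' R-native serialization (`saveRDS`/`readRDS`) of `area_dataset` and
#' `spike_encoder` objects.
#'
#' @param object object to save.
#' @param path file path.
#' @return `load_object` returns the restored object.
#' @export
save_object <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_object
#' @export
load_object <- function(path) readRDS(path)
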