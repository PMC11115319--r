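# Joint readouts over the channel-concatenation of two (or three) frozen
# cores. A single point readout (one position, one variance, one bias per
# neuron) spans the concatenated feature space; channel-weight blocks map
# one-to-one onto member cores, and warm-start strategies control which
# blocks are initialized from fitted single-core models and which are
# trainable.

#' The five pair-model training strategies
#'
#' @return Character vector of strategy names: fit everything from scratch;
#'   initialize block 1 (2) from its single-core model and fine-tune only
#'   block 2 (1); or initialize block 1 (2) and fine-tune all readout
#'   weights.
#' @export
pair_strategies <- function() {
  c("scratch", "init1_tune2", "init2_tune1", "init1_tune_all", "init2_tune_all")
}

block_mask <- function(C, blocks, trainable_blocks, N) {
  wmask <- matrix(0, N, C)
  gmask <- numeric(C)
  for (b in trainable_blocks) {
    wmask[, blocks[[b]]] <- 1
    gmask[blocks[[b]]] <- 1
  }
  list(w = wmask, g = gmask)
}

#' Initialize a pair readout from single-core checkpoints
#'
#' Builds an unfitted joint model over the concatenated feature space of two
#' fitted single-core models. Warm strategies copy the initialized block's
#' readout weights, the neuron positions (mean and variance), bias, and that
#' block's feature-head parameters and running statistics from the
#' corresponding single model; the other block's weights start at zero, so
#' before any training the joint model's predictions equal the initialized
#' single model's. The strategy records which parameters are trainable:
#' either only the other block's weights (and its head channels), or all
#' readout weights. Positions, variance and bias are trainable in every
#' strategy; `scratch` uses the default random initialization everywhere.
#'
#' @param singles list of two fitted `spike_encoder`s over the same neurons.
#' @param strategy one of [pair_strategies()].
#' @param seed seed for the scratch initialization.
#' @return An unfitted `spike_encoder` over the concatenated core, carrying
#'   a `"trainable"` mask and `"strategy"` attribute, ready for
#'   [fit_encoder()] (pass as `init`) or [predict()].
#' @export
init_pair_readout <- function(singles, strategy = pair_strategies(), seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(length(singles) == 2L)
  for (m in singles) stopifnot(inherits(m, "spike_encoder"))
  if (!identical(singles[[1]]$neurons$neuron_id, singles[[2]]$neurons$neuron_id)) {
    stop("single-core models must cover the same neurons in the same order")
  }
  if (!all(singles[[1]]$map_dim == singles[[2]]$map_dim)) {
    stop("member feature maps must share spatial dimensions")
  }
  core <- concat_core(singles[[1]]$core, singles[[2]]$core)
  blocks <- core$blocks
  C <- core$channels
  N <- nrow(singles[[1]]$neurons)

  params <- c(list(gamma = rep(1, C), beta = rep(0, C)),
              readout_init(N, C, seed = seed))
  head_state <- list(running_mean = rep(0, C), running_var = rep(1, C),
                     momentum = 0.1, eps = singles[[1]]$head_state$eps)

  copy_block <- function(b) {
    src <- singles[[b]]
    params$gamma[blocks[[b]]] <<- src$params$gamma
    params$beta[blocks[[b]]] <<- src$params$beta
    head_state$running_mean[blocks[[b]]] <<- src$head_state$running_mean
    head_state$running_var[blocks[[b]]] <<- src$head_state$running_var
    params$weights[, blocks[[b]]] <<- src$params$weights
    params$mu <<- src$params$mu
    params$rho <<- src$params$rho
    params$bias <<- src$params$bias
  }
  zero_block <- function(b) {
    params$weights[, blocks[[b]]] <<- 0
  }

  trainable_blocks <- switch(strategy,
    scratch = 1:2,
    init1_tune2 = { copy_block(1); zero_block(2); 2L },
    init2_tune1 = { copy_block(2); zero_block(1); 1L },
    init1_tune_all = { copy_block(1); zero_block(2); 1:2 },
    init2_tune_all = { copy_block(2); zero_block(1); 1:2 }
  )
  bm <- block_mask(C, blocks, trainable_blocks, N)
  trainable <- list(gamma = bm$g, beta = bm$g, mu = matrix(1, N, 2),
                    rho = rep(1, N), weights = bm$w, bias = rep(1, N))

  model <- structure(
    list(core = core, params = params, head_state = head_state,
         head = NULL, neurons = singles[[1]]$neurons, channels = C,
         map_dim = singles[[1]]$map_dim, lambda = NA_real_,
         schedule = NULL,
         history = data.frame(epoch = 0L, train_loss = NA_real_,
                              val_loss = NA_real_, lr = NA_real_),
         seed = seed),
    class = "spike_encoder"
  )
  attr(model, "trainable") <- trainable
  attr(model, "strategy") <- strategy
  model
}

#' Initialize a triplet readout from a fitted pair model
#'
#' The two blocks of a fitted pair model are copied (weights, head
#' parameters, running statistics, positions, variance, bias); the third
#' core's block starts at zero. All readout parameters are trainable.
#'
#' @param pair a fitted `spike_encoder` over a two-core concatenation.
#' @param core3 the third `feature_core`.
#' @return An unfitted `spike_encoder` over the three-core concatenation
#'   with a full trainable mask, strategy `"pair_init_tune_all"`.
#' @export
init_triplet_readout <- function(pair, core3) {
  stopifnot(inherits(pair, "spike_encoder"),
            inherits(pair$core, "concat_core"),
            length(pair$core$blocks) == 2L,
            inherits(core3, "feature_core"))
  core <- concat_core(pair$core$members[[1]], pair$core$members[[2]], core3)
  C <- core$channels
  N <- nrow(pair$neurons)
  Cp <- pair$channels
  params <- list(
    gamma = c(pair$params$gamma, rep(1, core3$channels)),
    beta = c(pair$params$beta, rep(0, core3$channels)),
    mu = pair$params$mu, rho = pair$params$rho,
    weights = cbind(pair$params$weights, matrix(0, N, core3$channels)),
    bias = pair$params$bias
  )
  head_state <- list(
    running_mean = c(pair$head_state$running_mean, rep(0, core3$channels)),
    running_var = c(pair$head_state$running_var, rep(1, core3$channels)),
    momentum = pair$head_state$momentum, eps = pair$head_state$eps
  )
  model <- structure(
    list(core = core, params = params, head_state = head_state, head = NULL,
         neurons = pair$neurons, channels = C, map_dim = pair$map_dim,
         lambda = NA_real_, schedule = NULL,
         history = data.frame(epoch = 0L, train_loss = NA_real_,
                              val_loss = NA_real_, lr = NA_real_),
         seed = pair$seed),
    class = "spike_encoder"
  )
  attr(model, "trainable") <- NULL
  attr(model, "strategy") <- "pair_init_tune_all"
  model
}

#' Fit a joint multi-core readout
#'
#' Convenience wrapper: initializes a pair (or triplet) model with the
#' requested strategy and fits it with the shared training engine,
#' restricted to the strategy's trainable parameter set. Parameters a
#' strategy declares frozen are bit-identical before and after fitting, and
#' the cores themselves stay frozen throughout.
#'
#' @param dataset an `area_dataset`.
#' @param singles list of two fitted single-core `spike_encoder`s (or a
#'   fitted pair model when `core3` is given).
#' @param strategy one of [pair_strategies()] (ignored for triplets).
#' @param core3 optional third core for triplet fitting.
#' @param lambda L1 penalty.
#' @param schedule a [make_schedule()].
#' @param seed integer seed.
#' @param verbose print per-epoch losses.
#' @return A fitted `spike_encoder` over the concatenated core, with the
#'   strategy recorded.
#' @export
fit_multicore <- function(dataset, singles, strategy = pair_strategies(),
                          core3 = NULL, lambda = 1,
                          schedule = make_schedule(), seed = 1,
                          verbose = FALSE) {
  if (is.null(core3)) {
    init <- init_pair_readout(singles, strategy, seed = seed)
  } else {
    init <- init_triplet_readout(singles, core3)
  }
  fit_encoder(dataset, init$core, lambda = lambda, schedule = schedule,
              seed = seed, init = init, verbose = verbose)
}
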