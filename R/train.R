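# Joint fitting of feature-head and readout parameters by Adam on the
# Poisson + L1 objective, with multi-session batch cycling, validation-based
# early stopping, learning-rate decay, and best-weight restoration.

#' Training schedule
#'
#' Bundles the optimizer and early-stopping constants. Defaults follow the
#' standard protocol for these models: initial learning rate 3e-4, decay
#' factor 0.3 once the validation loss fails to improve for 5 consecutive
#' epochs (with weights restored to the best-so-far before each decay),
#' stopping after 4 decay events, batch size 64 per session. The optimizer
#' is Adam; `beta1` defaults to 0.1 (the stated momentum, interpreted as the
#' first-moment coefficient) and is configurable.
#'
#' @param lr initial learning rate.
#' @param decay multiplicative learning-rate decay factor.
#' @param patience epochs without validation improvement before a decay.
#' @param max_events number of decay events after which fitting stops.
#' @param batch_size per-session batch size.
#' @param max_epochs hard cap on epochs (safety net).
#' @param beta1,beta2,adam_eps Adam moment coefficients and stabilizer.
#' @return An object of class `train_schedule`.
#' @export
make_schedule <- function(lr = 3e-4, decay = 0.3, patience = 5, max_events = 4,
                          batch_size = 64, max_epochs = 200, beta1 = 0.1,
                          beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(lr > 0, decay > 0, decay < 1, patience >= 1, max_events >= 1,
            batch_size >= 1, max_epochs >= 1)
  structure(
    list(lr = lr, decay = decay, patience = as.integer(patience),
         max_events = as.integer(max_events),
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
    class = "train_schedule"
  )
}

#' @export
print.train_schedule <- function(x, ...) {
  cat(sprintf(
    "<train_schedule> lr %.3g (x%.2g after %d stale epochs, %d events), batch %d\n",
    x$lr, x$decay, x$patience, x$max_events, x$batch_size
  ))
  invisible(x)
}

# Early-stopping / learning-rate controller as a pure state machine so the
# schedule contract is testable on a scripted loss sequence.
# State: best validation loss, epochs waited, decay events, current lr.
es_init <- function(schedule, initial_val = Inf) {
  list(best = initial_val, wait = 0L, events = 0L, lr = schedule$lr)
}

# Returns list(state, improved, decay, stop). `improved` means the caller
# should snapshot weights; `decay` means restore best weights then continue
# at the reduced lr; `stop` ends fitting (after the final decay event).
es_update <- function(state, val_loss, schedule) {
  improved <- val_loss < state$best
  decay <- FALSE
  stop_ <- FALSE
  if (improved) {
    state$best <- val_loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= schedule$patience) {
      decay <- TRUE
      state$lr <- state$lr * schedule$decay
      state$events <- state$events + 1L
      state$wait <- 0L
      if (state$events >= schedule$max_events) stop_ <- TRUE
    }
  }
  list(state = state, improved = improved, decay = decay, stop = stop_)
}

# Adam with gradients pre-masked by the trainable mask: frozen entries keep
# zero moments and receive no update.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, schedule) {
  state$t <- state$t + 1L
  b1 <- schedule$beta1; b2 <- schedule$beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + schedule$adam_eps)
  }
  list(params = params, state = state)
}

# Per-session sampling pool: batches drawn without replacement; an exhausted
# pool restarts from the full (reshuffled) set.
pool_init <- function(n) list(order = sample.int(n), ptr = 0L, n = n)

pool_draw <- function(pool, batch_size) {
  if (pool$ptr >= pool$n) {
    pool$order <- sample.int(pool$n)
    pool$ptr <- 0L
  }
  take <- min(batch_size, pool$n - pool$ptr)
  idx <- pool$order[(pool$ptr + 1L):(pool$ptr + take)]
  pool$ptr <- pool$ptr + take
  list(pool = pool, idx = idx)
}

#' Fit an encoding model across recording sessions
#'
#' Jointly learns the feature-head scale/shift and every neuron's point
#' readout (position mean and variance, channel weights, bias) by minimizing
#' the summed Poisson loss plus an L1 weight penalty. Each training step
#' cycles through all sessions, drawing one batch per session without
#' replacement and accumulating gradients before a single Adam update; an
#' epoch ends when the longest session is exhausted, and exhausted shorter
#' sessions restart from their full pool. Every epoch ends with a
#' frozen-statistics validation pass; the learning rate decays once
#' validation stalls for `patience` epochs (restoring the best weights
#' first), and fitting stops after `max_events` decays. The core is frozen
#' throughout: only feature-head and readout parameters change.
#'
#' @param dataset an `area_dataset` (see [assemble_area_dataset()]) or any
#'   list with a `sessions` list of per-session
#'   `train_images`/`train_counts`/`validation_images`/`validation_counts`.
#' @param core a `feature_core`.
#' @param lambda L1 penalty on readout feature weights.
#' @param schedule a [make_schedule()].
#' @param seed integer seed governing initialization, batch shuffling and
#'   position sampling.
#' @param init optional warm start: a `spike_encoder` (fitted or built by
#'   [init_pair_readout()]) whose parameters and running statistics are
#'   copied.
#' @param trainable optional mask (same shapes as the parameter list, 1 =
#'   trainable, 0 = frozen) restricting the update to a parameter subset.
#' @param position_init `"rf"` (default) starts each neuron's position at
#'   the feature-map pixel whose activations correlate best with its
#'   training responses (the model-space analogue of receptive-field
#'   mapping); `"center"` starts at the map center plus a small jitter.
#' @param verbose print per-epoch losses.
#' @return An object of class `spike_encoder` with the best-validation
#'   weights, running statistics, and a `history` data frame (epoch, train
#'   loss, validation loss, learning rate) with attributes `decay_epochs`
#'   and `best_epoch`.
#' @export
fit_encoder <- function(dataset, core, lambda = 1, schedule = make_schedule(),
                        seed = 1, init = NULL, trainable = NULL,
                        position_init = c("rf", "center"),
                        verbose = FALSE) {
  position_init <- match.arg(position_init)
  stopifnot(inherits(core, "feature_core"), inherits(schedule, "train_schedule"))
  sessions <- dataset$sessions
  if (is.null(sessions) || !length(sessions)) stop("dataset has no sessions")
  for (s in sessions) {
    if (is.null(s$validation_images) || !nrow_counts(s$validation_counts)) {
      stop("every session needs a validation split")
    }
  }

  # frozen core: features computed once
  Ftr <- lapply(sessions, function(s) core_features(core, s$train_images))
  Fva <- lapply(sessions, function(s) core_features(core, s$validation_images))
  fd <- dim(Ftr[[1]])
  H <- fd[2]; W <- fd[3]; C <- fd[4]
  stopifnot(C == core$channels)

  n_per <- vapply(sessions, function(s) ncol(s$train_counts), integer(1))
  offs <- cumsum(c(0L, n_per[-length(n_per)]))
  nidx <- Map(function(o, k) (o + 1L):(o + k), offs, n_per)
  N <- sum(n_per)
  neurons <- data.frame(
    global = seq_len(N),
    session = rep(vapply(sessions, function(s) as.character(s$session_id),
                         character(1)), n_per),
    neuron_id = unlist(lapply(sessions, function(s) s$neuron_ids)),
    stringsAsFactors = FALSE
  )

  if (is.null(init)) {
    # a broad position-sampling SD is needed to find distant receptive
    # fields from a center start; with the RF-mapped start a narrow SD
    # suffices and avoids blurring the readout
    init_sd <- if (position_init == "rf") 0.1 else 0.5
    params <- c(list(gamma = rep(1, C), beta = rep(0, C)),
                readout_init(N, C, init_sd = init_sd, seed = seed))
    # start each bias at the neuron's mean training response (through the
    # inverse output nonlinearity) so early gradients carry stimulus signal
    # rather than mean-rate mismatch
    mean_counts <- unlist(lapply(sessions,
                                 function(s) colMeans(s$train_counts)))
    params$bias <- ifelse(mean_counts >= 1, mean_counts - 1,
                          log(pmax(mean_counts, 0.01)))
    if (position_init == "rf") {
      params$mu <- rf_position_init(Ftr, lapply(sessions, `[[`, "train_counts"))
    }
    head_state <- list(running_mean = rep(0, C), running_var = rep(1, C),
                       momentum = 0.1, eps = 1e-5)
  } else {
    stopifnot(inherits(init, "spike_encoder"))
    params <- init$params
    head_state <- init$head_state
    if (is.null(trainable)) trainable <- attr(init, "trainable")
    stopifnot(nrow(params$mu) == N, ncol(params$weights) == C)
  }
  init_params <- params

  n_tr <- vapply(sessions, function(s) dim(s$train_images)[1], integer(1))
  n_cycles <- ceiling(max(n_tr) / schedule$batch_size)

  counts_tr <- lapply(sessions, function(s) s$train_counts)
  counts_va <- lapply(sessions, function(s) s$validation_counts)

  val_loss <- function(p, hs) {
    tot <- 0; nn <- 0L
    for (s in seq_along(sessions)) {
      ev <- session_eval(p, Fva[[s]], counts_va[[s]], nidx[[s]], hs)
      tot <- tot + ev$loss; nn <- nn + ev$n
    }
    tot / nn
  }

  fit_env <- with_seed(seed, {
    pools <- lapply(n_tr, pool_init)
    adam <- adam_init(params)
    v0 <- val_loss(params, head_state)
    es <- es_init(schedule, initial_val = v0)
    best <- list(params = params, head_state = head_state, epoch = 0L)
    hist <- data.frame(epoch = 0L, train_loss = NA_real_, val_loss = v0,
                       lr = schedule$lr)
    decay_epochs <- integer(0)
    if (verbose) message(sprintf("epoch   0  val %.5f", v0))

    for (epoch in seq_len(schedule$max_epochs)) {
      ep_loss <- 0; ep_n <- 0L
      for (cy in seq_len(n_cycles)) {
        total_grads <- zero_grads(params)
        for (s in seq_along(sessions)) {
          dr <- pool_draw(pools[[s]], schedule$batch_size)
          pools[[s]] <- dr$pool
          Z <- Ftr[[s]][dr$idx, , , , drop = FALSE]
          cb <- counts_tr[[s]][dr$idx, , drop = FALSE]
          eps_draws <- array(stats::rnorm(2 * length(dr$idx) * length(nidx[[s]])),
                             c(length(dr$idx), 2, length(nidx[[s]])))
          sg <- session_gradient(params, Z, cb, nidx[[s]], lambda, head_state,
                                 mode = "train", eps_draws = eps_draws)
          head_state <- sg$head_state
          total_grads <- add_grads(total_grads, sg$grads)
          ep_loss <- ep_loss + sg$loss
          ep_n <- ep_n + length(dr$idx)
        }
        if (!is.finite(ep_loss)) {
          stop(sprintf("non-finite training loss at epoch %d; try a smaller learning rate",
                       epoch))
        }
        total_grads <- scale_params(total_grads, trainable)
        st <- adam_step(params, total_grads, adam, es$lr, schedule)
        params <- st$params
        adam <- st$state
        params$mu <- clamp(params$mu, -1, 1)
      }

      v <- val_loss(params, head_state)
      if (!is.finite(v)) stop("non-finite validation loss; aborting fit")
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                                     val_loss = v, lr = es$lr))
      upd <- es_update(es, v, schedule)
      es <- upd$state
      if (upd$improved) {
        best <- list(params = params, head_state = head_state, epoch = epoch)
      }
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e%s", epoch,
                        ep_loss / ep_n, v, es$lr,
                        if (upd$decay) "  [decay]" else ""))
      }
      if (upd$decay) {
        params <- best$params
        head_state <- best$head_state
        decay_epochs <- c(decay_epochs, epoch)
      }
      if (upd$stop) break
    }
    list(best = best, hist = hist, decay_epochs = decay_epochs)
  })

  best <- fit_env$best
  hist <- fit_env$hist
  attr(hist, "decay_epochs") <- fit_env$decay_epochs
  attr(hist, "best_epoch") <- best$epoch

  head <- feature_head(C, momentum = best$head_state$momentum,
                       eps = best$head_state$eps)
  head$gamma <- best$params$gamma
  head$beta <- best$params$beta
  head$running_mean <- best$head_state$running_mean
  head$running_var <- best$head_state$running_var

  structure(
    list(
      core = core, params = best$params, head_state = best$head_state,
      head = head, neurons = neurons, channels = C, map_dim = c(H, W),
      lambda = lambda, schedule = schedule, history = hist, seed = seed,
      init_params = if (is.null(init)) NULL else init_params,
      strategy = if (is.null(init)) NULL else attr(init, "strategy")
    ),
    class = "spike_encoder"
  )
}

nrow_counts <- function(x) if (is.null(x)) 0L else nrow(x)

# Receptive-field-style position initialization: for each neuron, the map
# pixel whose channel activations correlate best (sum of squared Pearson
# correlations across channels) with the neuron's single-trial training
# responses, in relative coordinates. The analogue of experimental RF
# mapping, run on the model's own feature space.
rf_position_init <- function(feature_list, counts_list) {
  mus <- lapply(seq_along(feature_list), function(s) {
    Fs <- feature_list[[s]]
    d <- dim(Fs)
    B <- d[1]; H <- d[2]; W <- d[3]
    M <- matrix(Fs, nrow = B)                 # B x (H W C)
    Ms <- scale(M)
    Ms[is.na(Ms)] <- 0
    Cs <- scale(counts_list[[s]])
    Cs[is.na(Cs)] <- 0
    r2 <- (crossprod(Cs, Ms) / (B - 1))^2     # N x (H W C)
    t(apply(r2, 1, function(v) {
      score <- rowSums(matrix(v, H * W, d[4])) # sum over channels
      px <- arrayInd(which.max(score), c(H, W))
      c(
        if (W > 1) -1 + 2 * (px[2] - 1) / (W - 1) else 0,
        if (H > 1) -1 + 2 * (px[1] - 1) / (H - 1) else 0
      )
    }))
  })
  do.call(rbind, mus)
}
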