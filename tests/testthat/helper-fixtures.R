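# Shared fixtures, built once per test run and memoized. Everything is
# generated in code under fixed seeds; sizes are kept small so the whole
# suite runs in minutes on one CPU.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# two small Gabor banks with complementary orientation sets, plus an
# untrained control with matching map geometry
fix_core_cardinal <- function() memo("core_cardinal", function() {
  gabor_core(orientations = 2, frequencies = c(0.10, 0.18),
             id = "gabor_cardinal")
})

fix_core_oblique <- function() memo("core_oblique", function() {
  gabor_core(orientations = 2, frequencies = c(0.10, 0.18),
             orientation_offset = pi / 4, id = "gabor_oblique")
})

fix_core_untrained <- function() memo("core_untrained", function() {
  random_convnet_core(channels = c(8, 12, 8), strides = c(3, 1, 1),
                      seed = 4, id = "untrained")
})

# small single-session dataset whose ground truth mixes the two Gabor banks
fix_tiny_dataset <- function() memo("tiny_dataset", function() {
  assemble_area_dataset(
    n_sessions = 1, images_per_session = 160, n_test_images = 40,
    test_repeats = 10, neurons_per_session = 8,
    core = concat_core(fix_core_cardinal(), fix_core_oblique()),
    image_size = 32, weight_sparsity = 0.5, seed = 33
  )
})

fix_fast_schedule <- function() {
  make_schedule(lr = 1e-2, batch_size = 32, patience = 3, max_events = 1,
                max_epochs = 15)
}

# single-core fits on the tiny dataset, reused by multicore tests
fix_single_fit <- function(which = c("cardinal", "oblique")) {
  which <- match.arg(which)
  memo(paste0("single_", which), function() {
    core <- if (which == "cardinal") fix_core_cardinal() else fix_core_oblique()
    fit_encoder(fix_tiny_dataset(), core, lambda = 0.02,
                schedule = fix_fast_schedule(), seed = 1)
  })
}

# a valid handcrafted parameter set for a given core/neuron count, for
# contract tests that need a model but not a fitted one
manual_encoder <- function(core, n_neurons, map_dim, seed = 1) {
  C <- core$channels
  params <- c(list(gamma = rep(1, C), beta = rep(0, C)),
              readout_init(n_neurons, C, init_sd = 0.1, weight_sd = 0.3,
                           seed = seed))
  structure(
    list(core = core, params = params,
         head_state = list(running_mean = rep(0, C), running_var = rep(1, C),
                           momentum = 0.1, eps = 1e-5),
         head = NULL,
         neurons = data.frame(global = seq_len(n_neurons), session = "S01",
                              neuron_id = seq_len(n_neurons)),
         channels = C, map_dim = map_dim, lambda = 0, schedule = NULL,
         history = data.frame(epoch = 0L, train_loss = NA_real_,
                              val_loss = NA_real_, lr = NA_real_),
         seed = seed),
    class = "spike_encoder"
  )
}
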