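# Small, strongly separated training fixture shared by the training,
# importance and CLI tests (kept tiny so each fit takes ~1 s). Built
# once per test run and memoized.

local({
  cache <- new.env(parent = emptyenv())

  tiny_sim <<- function() {
    if (is.null(cache$sim)) {
      cache$sim <- simulate_multiomics(sim_config(
        n_samples = 90L, n_classes = 3L, n_features = c(25L, 25L, 15L),
        n_informative = 6L, effect_size = 3, shared_factor_dim = 2L,
        class_proportions = c(0.4, 0.35, 0.25), seed = 101))
    }
    cache$sim
  }

  tiny_config <<- function(...) {
    defaults <- list(k = 4L, hidden_dims = c(16L, 16L, 8L),
                     epochs_pretrain = 250L, epochs_main = 250L,
                     dropout = 0.3, ola_slots = 8L, ola_heads = 2L,
                     lr = 1e-3, seed = 7L)
    do.call(mogola_config, utils::modifyList(defaults, list(...)))
  }

  tiny_fit <<- function() {
    if (is.null(cache$fit)) {
      sim <- tiny_sim()
      sp <- make_splits(sim$dataset$labels, 0.3, 1L,
                        seed = 7)$repeats[[1L]]
      model <- fit_mogola(sim$dataset, sp$train_idx, tiny_config())
      cache$fit <- list(model = model, split = sp)
    }
    cache$fit
  }
})
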