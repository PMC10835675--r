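# Heavy fixtures built once per test run and cached across test files.

.dqf_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .dqf_cache)) {
    assign(name, builder(), envir = .dqf_cache)
  }
  get(name, envir = .dqf_cache)
}

# A compact model trained briefly on a synthetic panel: "trained" enough for
# attribution/attention tests to be meaningful, cheap enough to build once.
trained_small_model <- function() {
  cached("small_fit", function() {
    sp <- synthetic_params(n_probes = 400, length = 40, beta_gc = 0.8,
                           motif_effects = c(CTT = 0.3), noise_sd = 0.15,
                           seed = 11)
    panel <- simulate_panel(sp)
    cfg <- model_config(k = 3, d_model = 32, n_layers = 2, n_heads = 4,
                        ffn_dim = 64, max_len = 64, head_hidden = 32,
                        seed = 11)
    nz <- normalize_depths(panel$probes)
    fit <- train_model(depth_model(cfg), panel$probes, nz$params,
                       train_config(epochs = 8, batch_size = 32,
                                    learning_rate = 1e-3, seed = 11))
    list(model = fit$model, norm_params = nz$params, panel = panel)
  })
}

# The synthetic-recovery study: three seeds of the 2-layer/64-dim model on
# a 3000/1000 train/test split of the standard generator conditions.
recovery_runs <- function() {
  cached("recovery", function() {
    lapply(1:3, function(seed) {
      sp <- synthetic_params(n_probes = 4000, length = 60, beta_gc = 0.8,
                             motif_effects = c(CTT = 0.3), noise_sd = 0.15,
                             seed = seed)
      panel <- simulate_panel(sp)
      train <- panel$probes[1:3000, ]; class(train) <- class(panel$probes)
      test <- panel$probes[3001:4000, ]; class(test) <- class(panel$probes)
      cfg <- model_config(k = 3, d_model = 64, n_layers = 2, n_heads = 4,
                          ffn_dim = 128, max_len = 64, head_hidden = 64,
                          seed = seed)
      nz <- normalize_depths(train)
      fit <- train_model(depth_model(cfg), train, nz$params,
                         train_config(epochs = 30, batch_size = 64,
                                      learning_rate = 1e-3, seed = seed))
      pl <- predict(fit$model, test, nz$params)
      metrics <- compute_metrics(observed_log10(test, nz$params), pl)
      list(seed = seed, model = fit$model, norm_params = nz$params,
           test = test, metrics = metrics)
    })
  })
}
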