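test_that("metrics match hand-worked threshold cases", {
  m <- compute_metrics(c(1, 2), c(1.2, 1.8))
  expect_equal(m$rmse, 0.2, tolerance = 1e-12)
  expect_equal(m$f2acc, 1)       # 0.2 < log10(2) = 0.3010
  expect_equal(m$f3acc, 1)

  # constant shift of 0.4 brackets the two thresholds: log10(2) < 0.4 < log10(3)
  obs <- c(1, 1.5, 2.2, 3)
  m2 <- compute_metrics(obs, obs + 0.4)
  expect_equal(m2$f2acc, 0)
  expect_equal(m2$f3acc, 1)
  expect_equal(m2$pearson_r, 1, tolerance = 1e-12)
  expect_equal(m2$rmse, 0.4, tolerance = 1e-12)

  perfect <- compute_metrics(obs, obs)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$f2acc, 1)
})

test_that("metrics agree with a naive loop oracle on random vectors", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(2:60, 1)
    obs <- rnorm(n, 2, 0.5)
    pred <- obs + rnorm(n, 0, 0.3)
    got <- compute_metrics(obs, pred)
    want <- oracle_metrics(obs, pred)
    expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
    expect_equal(got$pearson_r, want$pearson_r, tolerance = 1e-12)
    expect_equal(got$f2acc, want$f2acc)
    expect_equal(got$f3acc, want$f3acc)
    expect_gte(got$f3acc, got$f2acc)   # nested thresholds
  }
})

test_that("Pearson's r is affine-invariant in predictions while RMSE is not", {
  set.seed(78)
  obs <- rnorm(40, 2, 0.6)
  pred <- obs + rnorm(40, 0, 0.2)
  base <- compute_metrics(obs, pred)
  scaled <- compute_metrics(obs, 0.5 * pred + 3)
  expect_equal(scaled$pearson_r, base$pearson_r, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(scaled$rmse, base$rmse)))
})

test_that("metrics reject degenerate input", {
  expect_error(compute_metrics(1:3, 1:2), "length mismatch")
  expect_error(compute_metrics(1, 1), "at least 2")
  expect_error(compute_metrics(c(1, 1), c(1, 2)), "zero variance")
})

test_that("training is deterministic under a fixed seed and validates input", {
  set.seed(55)
  probes <- probe_set(sprintf("p%d", 1:12), random_dna(12, 15),
                      10^runif(12, 0.5, 3))
  nz <- normalize_depths(probes)
  cfg <- model_config(k = 3, d_model = 8, n_layers = 1, n_heads = 2,
                      ffn_dim = 16, max_len = 32, head_hidden = 8, seed = 2)
  tc <- train_config(epochs = 3, batch_size = 4, learning_rate = 1e-3,
                     seed = 5)
  f1 <- train_model(depth_model(cfg), probes, nz$params, tc)
  f2 <- train_model(depth_model(cfg), probes, nz$params, tc)
  expect_identical(f1$history, f2$history)
  expect_equal(nrow(f1$history), 3)
  expect_error(train_config(epochs = 0), "epochs")
  empty <- probes[0, ]; class(empty) <- class(probes)
  expect_error(train_model(depth_model(cfg), empty, nz$params, tc),
               "empty training set")
})

test_that("training reduces the loss on a small panel", {
  set.seed(56)
  probes <- probe_set(sprintf("p%d", 1:24), random_dna(24, 15),
                      10^runif(24, 0.5, 3))
  nz <- normalize_depths(probes)
  cfg <- model_config(k = 3, d_model = 16, n_layers = 1, n_heads = 2,
                      ffn_dim = 32, max_len = 32, head_hidden = 16,
                      dropout = 0, seed = 2)
  tc <- train_config(epochs = 40, batch_size = 24, learning_rate = 3e-3,
                     seed = 5)
  fit <- train_model(depth_model(cfg), probes, nz$params, tc)
  expect_lt(fit$history$loss[40], fit$history$loss[1] * 0.5)
})

test_that("prediction output aligns with its input probes", {
  fit <- trained_small_model()
  sub <- fit$panel$probes[1:10, ]
  class(sub) <- class(fit$panel$probes)
  pl <- predict(fit$model, sub, fit$norm_params)
  expect_length(pl, 10)
  expect_named(pl, sub$probe_id)
  expect_true(all(is.finite(pl)))
  # duplicated probe gives an identical prediction
  expect_equal(unname(pl[1]),
               unname(predict(fit$model, sub$sequence[1], fit$norm_params)))
})

test_that("cross-validation partitions probes and guards against leakage", {
  set.seed(57)
  probes <- probe_set(sprintf("p%02d", 1:24), random_dna(24, 12),
                      10^runif(24, 0.5, 3))
  cfg <- model_config(k = 3, d_model = 8, n_layers = 1, n_heads = 2,
                      ffn_dim = 16, max_len = 32, head_hidden = 8, seed = 1)
  tc <- train_config(epochs = 1, batch_size = 8, learning_rate = 1e-3,
                     seed = 1)
  cv <- cross_validate(probes, cfg, tc, n_folds = 4, seed = 3)
  # every probe appears exactly once out-of-fold
  expect_equal(sort(cv$predictions$probe_id), sort(probes$probe_id))
  expect_length(cv$per_fold, 4)
  expect_equal(vapply(cv$per_fold, `[[`, numeric(1), "n"), rep(6, 4))
  expect_true(is.finite(cv$rmse_sd))

  # injecting an extreme probe into a held-out fold must not move the
  # training-fold normalization parameters of that fold
  victim <- probes$probe_id[unname(cv$folds[probes$probe_id]) == 0][1]
  probes2 <- probes
  probes2$observed_depth[probes2$probe_id == victim] <- 1e7
  class(probes2) <- class(probes)
  cv2 <- cross_validate(probes2, cfg, tc, n_folds = 4, seed = 3)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv2$fold_norm_params[[1]]$mean_log10,
               cv$fold_norm_params[[1]]$mean_log10, tolerance = 1e-12)
  expect_equal(cv2$fold_norm_params[[1]]$sd_log10,
               cv$fold_norm_params[[1]]$sd_log10, tolerance = 1e-12)
  # ...while folds that train on it do move
  expect_false(isTRUE(all.equal(cv2$fold_norm_params[[2]]$mean_log10,
                                cv$fold_norm_params[[2]]$mean_log10)))
})
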