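test_that("positional encoding matches its closed form", {
  pe <- positional_encoding(20, 16, base = 1000)
  # position 0: sines 0, cosines 1
  expect_equal(pe[1, seq(1, 16, 2)], rep(0, 8))
  expect_equal(pe[1, seq(2, 16, 2)], rep(1, 8))
  # direct evaluation of the formula at arbitrary entries
  for (pos in c(1, 7, 19)) {
    for (i in c(0, 3, 7)) {
      ang <- pos / 1000^(2 * i / 16)
      expect_equal(pe[pos + 1, 2 * i + 1], sin(ang), tolerance = 1e-12)
      expect_equal(pe[pos + 1, 2 * i + 2], cos(ang), tolerance = 1e-12)
    }
  }
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-12)   # pos=1, i=0, any base
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positional_encoding(10, 15), "even")
})

test_that("sin/cos column pairs sit on the unit circle everywhere", {
  pe <- positional_encoding(64, 32, base = 1000)
  ss <- pe[, seq(1, 32, 2)]^2 + pe[, seq(2, 32, 2)]^2
  expect_lt(max(abs(ss - 1)), 1e-12)
})

test_that("embedding is token lookup plus positional term", {
  m <- tiny_model()
  ids <- encode_pair("ACGTACGT", m$vocab)$forward_ids
  # zero token table leaves only the positional rows
  m0 <- m
  m0$params$tok_emb[] <- 0
  expect_equal(embed_tokens(ids, m0), m$pe[seq_along(ids), ])
  # same token at two positions differs exactly by the positional rows
  ids2 <- rep(5L, 6)
  E <- embed_tokens(ids2, m)
  expect_equal(E[1, ] - E[6, ], m$pe[1, ] - m$pe[6, ])
  expect_equal(dim(E), c(6L, m$config$d_model))
  expect_error(embed_tokens(1000L, m), "out of vocabulary")
})

test_that("compiled forward agrees with an independent pure-R reference", {
  skip_if_not_installed("pracma")
  set.seed(5)
  for (variant in list(list(), list(pooling = "mean"),
                       list(use_pam = FALSE),
                       list(tie_encoders = TRUE),
                       list(n_layers = 2, n_heads = 4, d_model = 16))) {
    m <- do.call(tiny_model, c(list(seed = 17), variant))
    for (s in random_dna(3, 12)) {
      expect_equal(model_forward(m, s), ref_forward_one(m, s),
                   tolerance = 1e-10)
    }
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(6)
  m <- tiny_model(seed = 21)
  seqs <- random_dna(3, 9)
  enc <- depthformer:::encode_panel(seqs, m$vocab)
  cfgc <- depthformer:::cfg_for_cpp(m$config)
  tg <- c(0.4, -0.7, 1.1)
  loss_at <- function(par)
    depthformer:::dqf_train_batch(par, cfgc, m$pe, enc$fwd, enc$rev,
                                  enc$lens, tg, FALSE, 1L, FALSE)$loss
  fb <- depthformer:::dqf_train_batch(m$params, cfgc, m$pe, enc$fwd,
                                      enc$rev, enc$lens, tg, FALSE, 1L,
                                      FALSE)
  h <- 1e-6
  for (nm in names(m$params)) {
    g <- fb$grads[[nm]]
    for (i in if (length(g) > 2) sample(length(g), 2) else seq_along(g)) {
      pp <- m$params
      pp[[nm]][i] <- pp[[nm]][i] + h
      up <- loss_at(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h
      dn <- loss_at(pp)
      num <- (up - dn) / (2 * h)
      expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-3)
    }
  }
})

test_that("forward pass is finite and deterministic on random probes", {
  m <- tiny_model(seed = 8, precision = "single", dropout = 0.1)
  set.seed(9)
  seqs <- random_dna(400, 20)
  p1 <- model_forward(m, seqs)
  expect_true(all(is.finite(p1)))
  expect_identical(p1, model_forward(m, seqs))  # eval mode: no dropout
  # duplicated probe gives identical predictions
  expect_equal(p1[1], model_forward(m, seqs[1]))
})

test_that("batching and padding do not change predictions", {
  m <- tiny_model(seed = 13, precision = "single")
  set.seed(14)
  seqs <- random_dna(12, sample(8:24, 12, replace = TRUE))  # ragged batch
  batched <- model_forward(m, seqs)
  single <- vapply(seqs, function(s) model_forward(m, s), numeric(1))
  expect_equal(batched, unname(single), tolerance = 1e-5)
})

test_that("tied encoders with a symmetric head are reverse-complement invariant", {
  m <- tiny_model(seed = 15, tie_encoders = TRUE, symmetric_head = TRUE)
  set.seed(16)
  for (s in random_dna(6, 15)) {
    expect_equal(model_forward(m, s),
                 model_forward(m, reverse_complement(s)), tolerance = 1e-8)
  }
  # untied concat head has no such symmetry
  m2 <- tiny_model(seed = 15)
  s <- random_dna(1, 15)
  expect_gt(abs(model_forward(m2, s) -
                model_forward(m2, reverse_complement(s))), 0)
})

test_that("single-strand ablation variant runs without the reverse branch", {
  m <- tiny_model(seed = 18, use_pam = FALSE)
  expect_false(any(grepl("^r1", names(m$params))))
  expect_equal(nrow(m$params$head.Wh), m$config$d_model)
  expect_true(is.finite(model_forward(m, "ACGTACGTAC")))
})

test_that("mse loss follows its definition", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(2, 0), c(1, 1)), 1)   # residuals 1, -1
  expect_equal(mse_loss(3, 1), 4)
  expect_error(mse_loss(1:3, 1:2), "length mismatch")
  expect_error(mse_loss(numeric(0), numeric(0)), "empty")
})

test_that("checkpoints reproduce predictions without the training panel", {
  fit <- trained_small_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, fit$norm_params, path)
  ck <- load_checkpoint(path)
  seqs <- fit$panel$probes$sequence[1:20]
  expect_identical(predict(ck$model, seqs, ck$norm_params),
                   predict(fit$model, seqs, fit$norm_params))
})

test_that("model_config enforces its invariants", {
  expect_error(model_config(d_model = 30, n_heads = 4), "divisible")
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(model_config(pooling = "first_token", prepend_cls = FALSE),
               "prepend_cls")
  expect_error(model_config(symmetric_head = TRUE, use_pam = FALSE),
               "symmetric_head")
})
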