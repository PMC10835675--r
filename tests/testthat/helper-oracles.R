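# Independent oracles used across test files.  These deliberately avoid the
# package's own code paths: loops and first-principles formulas only.

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = ""),
    character(1))
}

# Brute-force k-mer extraction: explicit substring loop.
oracle_kmers <- function(sequence, k) {
  out <- character(0)
  for (start in 1:(nchar(sequence) - k + 1))
    out <- c(out, substr(sequence, start, start + k - 1))
  out
}

# Naive metric reimplementation: scalar loops, textbook formulas.
oracle_metrics <- function(obs, pred) {
  n <- length(obs)
  ss <- 0
  for (j in seq_len(n)) ss <- ss + (obs[j] - pred[j])^2
  rmse <- sqrt(ss / n)
  mx <- sum(obs) / n; my <- sum(pred) / n
  num <- 0; dx <- 0; dy <- 0
  for (j in seq_len(n)) {
    num <- num + (obs[j] - mx) * (pred[j] - my)
    dx <- dx + (obs[j] - mx)^2
    dy <- dy + (pred[j] - my)^2
  }
  r <- num / (sqrt(dx) * sqrt(dy))
  c2 <- 0; c3 <- 0
  for (j in seq_len(n)) {
    e <- abs(obs[j] - pred[j])
    if (e < log10(2)) c2 <- c2 + 1
    if (e < log10(3)) c3 <- c3 + 1
  }
  list(rmse = rmse, pearson_r = r, f2acc = c2 / n, f3acc = c3 / n)
}

# Pure-R reference forward pass for the dual-encoder network (double
# precision, no dropout).  Written directly from the architecture
# description, independent of the compiled core.
ref_forward_one <- function(model, sequence) {
  cfg <- model$config
  p <- model$params
  ln <- function(X, g, b) {
    t(apply(X, 1, function(row) {
      mu <- mean(row)
      s <- sqrt(mean((row - mu)^2) + 1e-5)
      g * (row - mu) / s + b
    }))
  }
  gelu <- function(x) 0.5 * x * (1 + pracma::erf(x / sqrt(2)))
  encode_branch <- function(ids, prefix) {
    X <- p$tok_emb[ids + 1, , drop = FALSE] * sqrt(cfg$d_model) +
      model$pe[seq_along(ids), , drop = FALSE]
    d <- cfg$d_model; H <- cfg$n_heads; dh <- d / H
    for (l in seq_len(cfg$n_layers)) {
      nm <- function(s) p[[paste0(prefix, l, ".", s)]]
      Q <- X %*% nm("Wq") + matrix(nm("bq"), nrow(X), d, byrow = TRUE)
      K <- X %*% nm("Wk") + matrix(nm("bk"), nrow(X), d, byrow = TRUE)
      V <- X %*% nm("Wv") + matrix(nm("bv"), nrow(X), d, byrow = TRUE)
      Hc <- matrix(0, nrow(X), d)
      for (h in seq_len(H)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
        A <- t(apply(S, 1, function(row) exp(row - max(row)) /
                                          sum(exp(row - max(row)))))
        Hc[, cols] <- A %*% V[, cols, drop = FALSE]
      }
      O <- Hc %*% nm("Wo") + matrix(nm("bo"), nrow(X), d, byrow = TRUE)
      X <- ln(X + O, nm("ln1.g"), nm("ln1.b"))
      Fa <- gelu(X %*% nm("W1") + matrix(nm("b1"), nrow(X), cfg$ffn_dim,
                                         byrow = TRUE))
      G <- Fa %*% nm("W2") + matrix(nm("b2"), nrow(X), d, byrow = TRUE)
      X <- ln(X + G, nm("ln2.g"), nm("ln2.b"))
    }
    if (cfg$pooling == "first_token") X[1, ] else colMeans(X)
  }
  pair <- encode_pair(sequence, model$vocab, prepend_cls = cfg$prepend_cls)
  u <- encode_branch(pair$forward_ids, "f")
  if (cfg$use_pam) {
    v <- encode_branch(pair$reverse_ids, if (cfg$tie_encoders) "f" else "r")
    z <- if (cfg$symmetric_head) u + v else c(u, v)
  } else z <- u
  h1 <- pmax(0, as.vector(t(p$head.Wh) %*% z) + p$head.bh)
  sum(p$head.Wout * h1) + p$head.bout
}

# A small double-precision model for exactness tests.
tiny_model <- function(seed = 3, ...) {
  args <- list(k = 3, d_model = 8, n_layers = 1, n_heads = 2, ffn_dim = 16,
               dropout = 0, max_len = 32, head_hidden = 8,
               precision = "double", seed = seed)
  over <- list(...)
  args[names(over)] <- over
  depth_model(do.call(model_config, args))
}
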