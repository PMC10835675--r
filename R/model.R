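# The dual-encoder depth model: configuration, parameters, forward pass.

#' Model architecture configuration
#'
#' Collects every architecture hyperparameter of the depth model.  The
#' defaults follow the reference configuration: 3-mer tokens embedded in
#' 256 dimensions, six encoder layers of eight heads per strand, sinusoidal
#' positional encoding with base 1000, mean pooling and a paired
#' attention module (both strands encoded, representations concatenated).
#'
#' @param k k-mer size for tokenization.
#' @param d_model embedding / encoder width; must be divisible by `n_heads`.
#' @param n_layers encoder layers per strand.
#' @param n_heads attention heads per layer.
#' @param ffn_dim width of the position-wise feed-forward sublayer.
#' @param pe_base base of the sinusoidal positional encoding.  The default
#'   1000 follows the reference formulation; the canonical transformer value
#'   10000 is available by setting it here.
#' @param dropout dropout probability applied to each sublayer output
#'   during training (inactive at prediction time).
#' @param max_len maximum tokenized length (including the `<cls>` slot).
#' @param pooling how a strand's encoder output becomes one vector:
#'   `"mean"` (default) averages token positions, `"first_token"` reads the
#'   `<cls>` position.  Mean pooling is the default because with randomly
#'   initialized encoders the residual stream carries token content
#'   directly into the average, whereas the `<cls>` route only sees the
#'   sequence through attention outputs and trains poorly from scratch;
#'   first-token pooling is the natural choice when warm-starting from
#'   pretrained encoder weights.
#' @param use_pam paired attention module: encode the reverse complement
#'   with a second encoder and concatenate.  `FALSE` gives the single-strand
#'   ablation variant.
#' @param tie_encoders share encoder weights between the two strands.
#' @param symmetric_head sum the two strand vectors instead of
#'   concatenating, which (with tied encoders) makes the prediction exactly
#'   invariant to reverse complementation.
#' @param head_hidden hidden width of the two-layer regression head.
#' @param prepend_cls prepend a `<cls>` token to each strand (required for
#'   first-token pooling).
#' @param precision `"single"` (fast, used for training) or `"double"`
#'   (bit-accurate, used where exactness matters).
#' @param seed seed for parameter initialization.
#' @return A list of class `model_config`.
#' @export
model_config <- function(k = 3, d_model = 256, n_layers = 6, n_heads = 8,
                         ffn_dim = 4 * d_model, pe_base = 1000,
                         dropout = 0.1, max_len = 512,
                         pooling = c("mean", "first_token"),
                         use_pam = TRUE, tie_encoders = FALSE,
                         symmetric_head = FALSE, head_hidden = 256,
                         prepend_cls = TRUE,
                         precision = c("single", "double"), seed = 1) {
  pooling <- match.arg(pooling)
  precision <- match.arg(precision)
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  if (d_model %% 2 != 0) stop("d_model must be even for sinusoidal encoding")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (pooling == "first_token" && !prepend_cls)
    stop("first_token pooling requires prepend_cls = TRUE")
  if (symmetric_head && !use_pam)
    stop("symmetric_head requires use_pam = TRUE")
  structure(list(k = as.integer(k), d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 ffn_dim = as.integer(ffn_dim), pe_base = pe_base,
                 dropout = dropout, max_len = as.integer(max_len),
                 pooling = pooling, use_pam = use_pam,
                 tie_encoders = tie_encoders, symmetric_head = symmetric_head,
                 head_hidden = as.integer(head_hidden),
                 prepend_cls = prepend_cls, precision = precision,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Sinusoidal positional encoding matrix
#'
#' Entry `(pos, 2i)` is `sin(pos / base^(2i/d_model))` and entry
#' `(pos, 2i+1)` is `cos(pos / base^(2i/d_model))`, with `pos` and `i`
#' 0-based; every sin/cos column pair therefore lies on the unit circle at
#' every position.
#'
#' @param max_len number of positions (rows).
#' @param d_model embedding width (columns); must be even.
#' @param base denominator base; 1000 by default.
#' @return A `max_len x d_model` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(max_len, d_model, base = 1000) {
  if (d_model %% 2 != 0) stop("d_model must be even")
  pos <- seq_len(max_len) - 1
  i2 <- 2 * (seq_len(d_model / 2) - 1)          # 0, 2, 4, ...
  ang <- outer(pos, base^(i2 / d_model), "/")   # max_len x d_model/2
  pe <- matrix(0, max_len, d_model)
  pe[, seq(1, d_model, by = 2)] <- sin(ang)
  pe[, seq(2, d_model, by = 2)] <- cos(ang)
  pe
}

# 0 = first_token, 1 = mean; mirrored in the compiled core.
pooling_code <- function(pooling) match(pooling, c("first_token", "mean")) - 1L

# Config view handed to the compiled core.
cfg_for_cpp <- function(config) {
  list(d_model = config$d_model, n_heads = config$n_heads,
       n_layers = config$n_layers, ffn_dim = config$ffn_dim,
       pooling_code = pooling_code(config$pooling),
       use_pam = config$use_pam, tie_encoders = config$tie_encoders,
       symmetric_head = config$symmetric_head, dropout = config$dropout)
}

layer_param_names <- function(prefix) {
  paste0(prefix, ".", c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
                        "W1", "b1", "W2", "b2",
                        "ln1.g", "ln1.b", "ln2.g", "ln2.b"))
}

init_layer <- function(d, ffn, sd0) {
  W <- function(nr, nc) matrix(rnorm(nr * nc, sd = sd0), nr, nc)
  list(Wq = W(d, d), bq = numeric(d), Wk = W(d, d), bk = numeric(d),
       Wv = W(d, d), bv = numeric(d), Wo = W(d, d), bo = numeric(d),
       W1 = W(d, ffn), b1 = numeric(ffn), W2 = W(ffn, d), b2 = numeric(d),
       ln1.g = rep(1, d), ln1.b = numeric(d),
       ln2.g = rep(1, d), ln2.b = numeric(d))
}

head_input_dim <- function(config) {
  if (!config$use_pam) config$d_model
  else if (config$symmetric_head) config$d_model
  else 2L * config$d_model
}

#' Initialize a depth model
#'
#' Builds the vocabulary (unless supplied), the fixed positional-encoding
#' table and randomly initialized parameters: all weight matrices drawn
#' from `N(0, 0.02^2)`, biases zero, layer-norm gains one.  The token
#' embedding table is shared between the two strand encoders; the encoder
#' weights themselves are independent unless `tie_encoders` is set.
#' Externally trained parameters of matching shapes can be injected via
#' `params` (an optional warm-start hook).
#'
#' @param config a [model_config()].
#' @param vocab optional [build_vocab()] vocabulary (must match `config$k`).
#' @param params optional named list of parameters to start from.
#' @return An object of class `depth_model`: list with `params` (named list
#'   of matrices/vectors), `config`, `vocab` and the positional table `pe`.
#' @export
depth_model <- function(config = model_config(), vocab = NULL, params = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(vocab)) vocab <- build_vocab(config$k)
  if (vocab$k != config$k) stop("vocabulary k does not match config k")
  d <- config$d_model
  if (is.null(params)) {
    params <- with_seed(config$seed, {
      sd0 <- 0.02
      p <- list(tok_emb = matrix(rnorm(length(vocab$id_to_token) * d, sd = sd0),
                                 length(vocab$id_to_token), d))
      for (l in seq_len(config$n_layers))
        p[layer_param_names(paste0("f", l))] <- init_layer(d, config$ffn_dim, sd0)
      if (config$use_pam && !config$tie_encoders)
        for (l in seq_len(config$n_layers))
          p[layer_param_names(paste0("r", l))] <- init_layer(d, config$ffn_dim, sd0)
      zd <- head_input_dim(config)
      p$head.Wh <- matrix(rnorm(zd * config$head_hidden, sd = sd0),
                          zd, config$head_hidden)
      p$head.bh <- numeric(config$head_hidden)
      p$head.Wout <- rnorm(config$head_hidden, sd = sd0)
      p$head.bout <- 0
      p
    })
  }
  structure(list(params = params, config = config, vocab = vocab,
                 pe = positional_encoding(config$max_len, d, config$pe_base)),
            class = "depth_model")
}

#' @export
print.depth_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(paste0("<depth_model> k=%d d_model=%d layers=%d heads=%d ",
                     "ffn=%d pooling=%s pam=%s (%s params)\n"),
              cfg$k, cfg$d_model, cfg$n_layers, cfg$n_heads, cfg$ffn_dim,
              cfg$pooling, cfg$use_pam, format(n_par, big.mark = ",")))
  invisible(x)
}

#' Input embeddings for a token id sequence
#'
#' Row `t` is the token embedding of the t-th id, scaled by
#' `sqrt(d_model)` (the canonical balance against the unit-amplitude
#' sinusoidal positional term), plus the positional encoding of position
#' `t` — the matrix the encoder stack consumes.
#'
#' @param ids 0-based integer token ids (one strand of a
#'   [encode_pair()] result).
#' @param model a [depth_model()].
#' @return A `length(ids) x d_model` matrix.
#' @export
embed_tokens <- function(ids, model) {
  stopifnot(inherits(model, "depth_model"))
  if (any(ids < 0 | ids >= nrow(model$params$tok_emb)))
    stop("token id out of vocabulary range")
  model$params$tok_emb[ids + 1L, , drop = FALSE] *
    sqrt(model$config$d_model) +
    model$pe[seq_along(ids), , drop = FALSE]
}

# Padded id matrices for a character vector of sequences.
model_encode <- function(model, sequences) {
  enc <- encode_panel(sequences, model$vocab,
                      prepend_cls = model$config$prepend_cls)
  if (max(enc$lens) > model$config$max_len)
    stop("tokenized length exceeds config max_len")
  enc
}

#' Forward pass: predicted normalized depth per sequence
#'
#' Runs the dual-encoder network in evaluation mode (no dropout) and
#' returns one scalar per input sequence on the normalized (z-scored
#' log10 depth) scale.
#'
#' @param model a [depth_model()].
#' @param sequences character vector of probe sequences.
#' @return numeric vector of predictions.
#' @export
model_forward <- function(model, sequences) {
  enc <- model_encode(model, sequences)
  dqf_predict_batch(model$params, cfg_for_cpp(model$config), model$pe,
                    enc$fwd, enc$rev, enc$lens,
                    model$config$precision == "single")
}

#' Mean squared error loss
#'
#' @param predicted,observed equal-length numeric vectors (normalized
#'   depths).
#' @return mean of squared residuals.
#' @export
mse_loss <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) == 0) stop("empty input")
  mean((predicted - observed)^2)
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles weights, architecture config, vocabulary and the
#' depth-normalization parameters — everything needed to predict on a new
#' FASTA without the training panel.
#'
#' @param model a trained [depth_model()].
#' @param norm_params the `depth_norm_params` the model was trained with.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `model` and `norm_params`.
#' @export
save_checkpoint <- function(model, norm_params, path) {
  stopifnot(inherits(model, "depth_model"),
            inherits(norm_params, "depth_norm_params"))
  saveRDS(list(params = model$params, config = model$config,
               vocab_k = model$vocab$k, norm_params = norm_params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- depth_model(ck$config, vocab = build_vocab(ck$vocab_k),
                       params = ck$params)
  list(model = model, norm_params = ck$norm_params)
}
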