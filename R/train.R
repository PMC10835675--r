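# Training loop (AdamW), prediction, evaluation metrics, cross-validation.

#' Training configuration
#'
#' @param epochs passes over the training panel.
#' @param batch_size sequences per gradient step.
#' @param learning_rate constant AdamW learning rate.
#' @param optimizer `"adamw"`, `"adam"` (no decoupled decay) or `"sgd"`.
#' @param weight_decay decoupled weight decay (AdamW only).
#' @param grad_clip global gradient-norm clip; `Inf` disables clipping.
#' @param seed seed controlling shuffling and dropout; a fixed seed gives
#'   an identical loss history on identical hardware/thread settings.
#' @param early_stop_patience stop when the epoch training loss has not
#'   improved for this many epochs (`NULL` disables).
#' @param max_steps optional cap on total gradient steps (overrides
#'   `epochs` when reached first).
#' @param target_rmse optional early exit once the epoch training RMSE
#'   (normalized scale) falls below this value.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 32, learning_rate = 1e-4,
                         optimizer = c("adamw", "adam", "sgd"),
                         weight_decay = 0.01, grad_clip = 1.0, seed = 1,
                         early_stop_patience = NULL, max_steps = NULL,
                         target_rmse = NULL) {
  optimizer <- match.arg(optimizer)
  if (epochs < 1) stop("epochs must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 weight_decay = weight_decay, grad_clip = grad_clip,
                 seed = as.integer(seed),
                 early_stop_patience = early_stop_patience,
                 max_steps = max_steps, target_rmse = target_rmse),
            class = "train_config")
}

# One AdamW/Adam/SGD update in place on the parameter list.
optim_step <- function(params, grads, state, cfg) {
  lr <- cfg$learning_rate
  if (cfg$optimizer == "sgd") {
    for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
    return(list(params = params, state = state))
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (cfg$optimizer == "adamw" && cfg$weight_decay > 0)
      upd <- upd + cfg$weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (total > max_norm) grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

#' Train a depth model
#'
#' Minimizes mean squared error between the model output and normalized
#' observed depths by minibatch gradient descent.  Shuffling and dropout
#' are driven by a local RNG seeded from `train_cfg$seed`, so a fixed seed
#' reproduces the loss history exactly.
#'
#' @param model a freshly initialized or warm [depth_model()].
#' @param probes the training [probe_set()].
#' @param norm_params `depth_norm_params` fitted on the training depths
#'   (see [normalize_depths()]); targets are
#'   `(log10(depth + pseudocount) - mean) / sd`.
#' @param train_cfg a [train_config()].
#' @return A list: `model` (trained), `history` (data frame with one row
#'   per completed epoch: `epoch`, `loss`, `rmse`), `steps` (gradient steps
#'   taken).
#' @export
train_model <- function(model, probes, norm_params, train_cfg = train_config()) {
  stopifnot(inherits(model, "depth_model"),
            inherits(train_cfg, "train_config"))
  if (nrow(probes) == 0) stop("empty training set")
  enc <- model_encode(model, probes$sequence)
  targets <- (observed_log10(probes, norm_params) - norm_params$mean_log10) /
    norm_params$sd_log10
  cfgc <- cfg_for_cpp(model$config)
  single <- model$config$precision == "single"
  params <- model$params
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  n <- nrow(probes)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        rmse = numeric(0))
  steps <- 0L
  best <- Inf; stale <- 0L
  with_seed(train_cfg$seed, {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
      ep_loss <- 0
      for (b in batches) {
        step_seed <- sample.int(.Machine$integer.max, 1)
        res <- dqf_train_batch(params, cfgc, model$pe,
                               enc$fwd[b, , drop = FALSE],
                               enc$rev[b, , drop = FALSE],
                               enc$lens[b], targets[b],
                               TRUE, step_seed, single)
        if (!is.finite(res$loss))
          stop(sprintf("non-finite loss at step %d; lower the learning rate",
                       steps + 1L))
        grads <- clip_grads(res$grads, train_cfg$grad_clip)
        os <- optim_step(params, grads, state, train_cfg)
        params <- os$params; state <- os$state
        ep_loss <- ep_loss + res$loss * length(b)
        steps <- steps + 1L
        if (!is.null(train_cfg$max_steps) && steps >= train_cfg$max_steps) break
      }
      ep_loss <- ep_loss / n
      history <- rbind(history, data.frame(epoch = epoch, loss = ep_loss,
                                           rmse = sqrt(ep_loss)))
      if (!is.null(train_cfg$target_rmse) &&
          sqrt(ep_loss) < train_cfg$target_rmse) break
      if (!is.null(train_cfg$max_steps) && steps >= train_cfg$max_steps) break
      if (!is.null(train_cfg$early_stop_patience)) {
        if (ep_loss < best - 1e-12) { best <- ep_loss; stale <- 0L }
        else {
          stale <- stale + 1L
          if (stale >= train_cfg$early_stop_patience) break
        }
      }
    }
  })
  model$params <- params
  list(model = model, history = history, steps = steps)
}

#' Predict log10 depths for a probe set
#'
#' Evaluation-mode forward passes, denormalized to the
#' `log10(depth + pseudocount)` scale via the training normalization
#' parameters.
#'
#' @param object a trained [depth_model()].
#' @param probes a [probe_set()] (or character vector of sequences).
#' @param norm_params the `depth_norm_params` used in training.
#' @param batch_size sequences per forward batch.
#' @param ... unused.
#' @return named numeric vector of predicted log10 depths, in input order.
#' @export
predict.depth_model <- function(object, probes, norm_params,
                                batch_size = 256, ...) {
  seqs <- if (inherits(probes, "probe_set")) probes$sequence
          else as.character(probes)
  ids <- if (inherits(probes, "probe_set")) probes$probe_id else names(seqs)
  preds <- numeric(length(seqs))
  for (start in seq(1, length(seqs), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(seqs))
    preds[idx] <- model_forward(object, seqs[idx])
  }
  out <- denormalize(preds, norm_params)
  if (!is.null(ids)) names(out) <- ids
  out
}

#' Depth-prediction accuracy metrics
#'
#' Computes, on the log10 depth scale: RMSE (root mean squared error),
#' Pearson's r, and the factor-of-N accuracies F2acc and F3acc — the
#' fraction of probes whose prediction is within a factor 2 (resp. 3) of
#' the observation, i.e. `|log10(obs) - log10(pred)| < log10(2)` (resp.
#' `log10(3)`).  F3acc >= F2acc by construction.
#'
#' @param observed_log10,predicted_log10 equal-length numeric vectors on
#'   the log10 depth scale.
#' @param factors accuracy factors to report (default 2 and 3).
#' @return A list of class `metrics_report`: `rmse`, `pearson_r`, `f2acc`,
#'   `f3acc`, `n`.
#' @examples
#' compute_metrics(c(1, 2), c(1.2, 1.8))  # rmse 0.2, F2acc 1
#' @export
compute_metrics <- function(observed_log10, predicted_log10,
                            factors = c(2, 3)) {
  if (length(observed_log10) != length(predicted_log10))
    stop("length mismatch between observed and predicted")
  if (length(observed_log10) < 2) stop("need at least 2 observations")
  if (stats::sd(observed_log10) == 0 || stats::sd(predicted_log10) == 0)
    stop("zero variance: Pearson's r undefined")
  err <- abs(observed_log10 - predicted_log10)
  facc <- vapply(factors, function(f) mean(err < log10(f)), numeric(1))
  structure(list(rmse = sqrt(mean(err^2)),
                 pearson_r = stats::cor(observed_log10, predicted_log10),
                 f2acc = facc[1], f3acc = facc[2],
                 n = length(observed_log10)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  RMSE=%.4f  r=%.4f  F2acc=%.2f%%  F3acc=%.2f%%\n",
              x$n, x$rmse, x$pearson_r, 100 * x$f2acc, 100 * x$f3acc))
  invisible(x)
}

#' @method as.data.frame metrics_report
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(rmse = x$rmse, pearson_r = x$pearson_r, f2acc = x$f2acc,
             f3acc = x$f3acc, n = x$n)
}

#' k-fold cross-validation of the depth model
#'
#' For each fold a fresh model is initialized and trained on the remaining
#' folds; depth normalization is fitted on the training folds only, so no
#' information from held-out probes leaks into the targets.  Metrics are
#' reported per fold and pooled over the concatenated out-of-fold
#' predictions, together with the standard deviation of RMSE across folds.
#'
#' @param probes a [probe_set()].
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param n_folds number of folds.
#' @param seed seed for the fold split and per-fold model initialization.
#' @param pseudocount depth pseudocount used throughout.
#' @return A list of class `cv_result`: `per_fold` (list of
#'   `metrics_report`), `pooled` (`metrics_report` over all out-of-fold
#'   predictions), `rmse_sd` (sd of per-fold RMSE), `folds`
#'   (`fold_assignment`) and `predictions` (data frame with `probe_id`,
#'   `fold`, `observed_depth`, `observed_log10`, `predicted_log10`,
#'   `abs_log10_error`).
#' @export
cross_validate <- function(probes, model_cfg, train_cfg, n_folds = 5,
                           seed = 1, pseudocount = 1) {
  folds <- make_cv_folds(probes, n_folds, seed)
  fold_of <- unname(folds[probes$probe_id])
  preds <- vector("list", n_folds)
  per_fold <- vector("list", n_folds)
  fold_norm <- vector("list", n_folds)
  for (f in seq_len(n_folds) - 1L) {
    train_idx <- which(fold_of != f)
    test_idx <- which(fold_of == f)
    train_probes <- probes[train_idx, ]
    class(train_probes) <- class(probes)
    nz <- normalize_depths(train_probes, pseudocount)
    fold_norm[[f + 1L]] <- nz$params
    cfg_f <- model_cfg
    cfg_f$seed <- model_cfg$seed + f
    fit <- train_model(depth_model(cfg_f), train_probes, nz$params, train_cfg)
    test_probes <- probes[test_idx, ]
    class(test_probes) <- class(probes)
    pl <- predict(fit$model, test_probes, nz$params)
    ol <- observed_log10(test_probes, nz$params)
    per_fold[[f + 1L]] <- compute_metrics(ol, pl)
    preds[[f + 1L]] <- data.frame(probe_id = test_probes$probe_id, fold = f,
                                  observed_depth = test_probes$observed_depth,
                                  observed_log10 = ol, predicted_log10 = pl,
                                  abs_log10_error = abs(ol - pl),
                                  stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  pooled <- compute_metrics(predictions$observed_log10,
                            predictions$predicted_log10)
  structure(list(per_fold = per_fold, pooled = pooled,
                 rmse_sd = stats::sd(vapply(per_fold, `[[`, numeric(1), "rmse")),
                 folds = folds, fold_norm_params = fold_norm,
                 predictions = predictions),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, pooled out-of-fold metrics:\n",
              length(x$per_fold)))
  print(x$pooled)
  cat(sprintf("per-fold RMSE sd: %.4f\n", x$rmse_sd))
  invisible(x)
}
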