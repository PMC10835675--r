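# Model interpretation: attention-score aggregation, integrated gradients,
# extreme-depth probe extraction, k-mer enrichment, thermodynamic rank
# correlation.

#' Aggregate attention scores per layer and head
#'
#' For each strand encoder, layer and head, sums the softmax attention
#' weights over all query/key token pairs and over all sequences.  Because
#' softmax rows sum to one, a single sequence of T query positions
#' contributes exactly T per head, so the aggregate is conserved and
#' additive over the dataset; differences between heads appear once
#' attention is compared at finer grain, and differences between the two
#' strand matrices reflect genuinely distinct encoder weights.
#'
#' @param model a trained [depth_model()].
#' @param probes a [probe_set()] or character vector of sequences.
#' @param per_sequence also return the per-sequence score cubes.
#' @param batch_size sequences per forward batch.
#' @return A list of class `attention_summary`: `forward` and `reverse`
#'   (`n_layers x n_heads` aggregated-score matrices; `reverse` is `NULL`
#'   without the paired attention module), `forward_conc` / `reverse_conc`
#'   (same shape, summed squared attention weights — a concentration
#'   profile that, unlike the conserved score, genuinely distinguishes
#'   heads and branches), `n_sequences`, `total_queries` (sum of tokenized
#'   lengths) and optionally `per_sequence` (list of cubes
#'   `n_layers x n_heads x n`).
#' @export
attention_scores <- function(model, probes, per_sequence = FALSE,
                             batch_size = 256) {
  stopifnot(inherits(model, "depth_model"))
  seqs <- if (inherits(probes, "probe_set")) probes$sequence
          else as.character(probes)
  if (length(seqs) == 0) stop("empty probe set")
  cfgc <- cfg_for_cpp(model$config)
  single <- model$config$precision == "single"
  L <- model$config$n_layers; H <- model$config$n_heads
  fwd_sum <- matrix(0, L, H)
  rev_sum <- matrix(0, L, H)
  fwd_conc <- matrix(0, L, H)
  rev_conc <- matrix(0, L, H)
  ps_f <- list(); ps_r <- list()
  total_queries <- 0L
  for (start in seq(1, length(seqs), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(seqs))
    enc <- model_encode(model, seqs[idx])
    res <- dqf_attention_batch(model$params, cfgc, model$pe,
                               enc$fwd, enc$rev, enc$lens, single)
    fwd_sum <- fwd_sum + apply(res$forward, c(1, 2), sum)
    fwd_conc <- fwd_conc + apply(res$forward_conc, c(1, 2), sum)
    if (model$config$use_pam) {
      rev_sum <- rev_sum + apply(res$reverse, c(1, 2), sum)
      rev_conc <- rev_conc + apply(res$reverse_conc, c(1, 2), sum)
    }
    total_queries <- total_queries + sum(enc$lens)
    if (per_sequence) {
      ps_f[[length(ps_f) + 1L]] <- res$forward
      ps_r[[length(ps_r) + 1L]] <- res$reverse
    }
  }
  dimnames(fwd_sum) <- list(layer = seq_len(L), head = seq_len(H))
  dimnames(fwd_conc) <- dimnames(fwd_sum)
  out <- list(forward = fwd_sum,
              reverse = if (model$config$use_pam) {
                dimnames(rev_sum) <- dimnames(fwd_sum); rev_sum
              },
              forward_conc = fwd_conc,
              reverse_conc = if (model$config$use_pam) {
                dimnames(rev_conc) <- dimnames(fwd_sum); rev_conc
              },
              n_sequences = length(seqs), total_queries = total_queries)
  if (per_sequence) {
    bind3 <- function(lst) {
      arr <- array(0, c(L, H, sum(vapply(lst, function(a) dim(a)[3], 0))))
      at <- 0L
      for (a in lst) { arr[, , at + seq_len(dim(a)[3])] <- a; at <- at + dim(a)[3] }
      arr
    }
    out$per_sequence <- list(forward = bind3(ps_f),
                             reverse = if (model$config$use_pam) bind3(ps_r))
  }
  structure(out, class = "attention_summary")
}

#' @export
print.attention_summary <- function(x, ...) {
  cat(sprintf("<attention_summary> %d sequences, %d layers x %d heads\n",
              x$n_sequences, nrow(x$forward), ncol(x$forward)))
  invisible(x)
}

#' Long-format table of an attention summary
#'
#' One row per (branch, layer, head) with the aggregated score —
#' heatmap-ready (head on the x-axis, layer on the y-axis).
#'
#' @param x an [attention_scores()] result.
#' @param ... unused.
#' @return A data frame with columns `branch`, `layer`, `head`, `score`,
#'   `concentration`.
#' @method as.data.frame attention_summary
#' @export
as.data.frame.attention_summary <- function(x, ...) {
  long <- function(m, conc, branch)
    data.frame(branch = branch,
               layer = rep(seq_len(nrow(m)), ncol(m)),
               head = rep(seq_len(ncol(m)), each = nrow(m)),
               score = as.vector(m), concentration = as.vector(conc))
  out <- long(x$forward, x$forward_conc, "forward")
  if (!is.null(x$reverse))
    out <- rbind(out, long(x$reverse, x$reverse_conc, "reverse"))
  out
}

#' Integrated gradients along a straight embedding path
#'
#' Midpoint Riemann approximation of the path integral of gradients from a
#' baseline to an input, for an arbitrary differentiable function.  Exact
#' for linear functions at any step count; for the depth model use
#' [integrated_gradients()], which wraps this around the compiled network.
#'
#' @param grad_fn function(x) returning the gradient of the scalar output
#'   at `x` (same shape as `x`).
#' @param x input (numeric vector or matrix).
#' @param baseline baseline of the same shape.
#' @param steps number of Riemann steps.
#' @return elementwise attributions of the same shape as `x`, summing to
#'   approximately `f(x) - f(baseline)`.
#' @export
ig_riemann <- function(grad_fn, x, baseline, steps) {
  if (steps < 1) stop("steps must be >= 1")
  diff <- x - baseline
  acc <- x * 0
  for (s in seq_len(steps)) {
    alpha <- (s - 0.5) / steps
    acc <- acc + grad_fn(baseline + alpha * diff)
  }
  diff * acc / steps
}

#' Per-token integrated gradients for one probe
#'
#' Attribution of the model's (normalized-scale) depth prediction to each
#' token position.  Both strand branches are attributed against a shared
#' baseline and the reverse-complement branch is mapped back to forward
#' coordinates (reverse token position p corresponds to forward position
#' T-1-p) and summed, so `ig_values` lives on the forward token axis.  The
#' completeness gap `f(x) - f(baseline) - sum(IG)` is computed and stored,
#' never assumed.
#'
#' @param model a trained [depth_model()].
#' @param sequence a single probe sequence (or a one-row [probe_set()]).
#' @param steps Riemann steps (>= 8).
#' @param baseline `"pad"` (all-`<pad>`-token embedding, the default
#'   near-zero-information input) or `"zero"` (all-zero embedding matrix).
#' @param probe_id optional id carried into the result.
#' @return A list of class `attribution_result`: `probe_id`, `tokens`
#'   (forward tokens incl. `<cls>` if used), `ig_values` (combined, forward
#'   coordinates), `ig_forward`, `ig_reverse_mapped`, `prediction`,
#'   `baseline_prediction`, `completeness_gap`, `steps`.
#' @export
integrated_gradients <- function(model, sequence, steps = 64,
                                 baseline = c("pad", "zero"),
                                 probe_id = NULL) {
  stopifnot(inherits(model, "depth_model"))
  baseline <- match.arg(baseline)
  if (steps < 8) stop("steps must be >= 8")
  if (inherits(sequence, "probe_set")) {
    if (nrow(sequence) != 1) stop("pass a single probe")
    probe_id <- sequence$probe_id
    sequence <- sequence$sequence
  }
  cfg <- model$config
  pair <- encode_pair(sequence, model$vocab, prepend_cls = cfg$prepend_cls)
  Tlen <- length(pair$forward_ids)
  Xf <- embed_tokens(pair$forward_ids, model)
  Xr <- embed_tokens(pair$reverse_ids, model)
  Bx <- switch(baseline,
               pad = embed_tokens(rep(PAD_ID, Tlen), model),
               zero = matrix(0, Tlen, cfg$d_model))
  cfgc <- cfg_for_cpp(cfg)
  single <- cfg$precision == "single"
  run <- function(cube_f, cube_r) {
    dqf_embed_grad_batch(model$params, cfgc, cube_f, cube_r,
                         rep(Tlen, dim(cube_f)[3]), single)
  }
  stack <- function(X, B) {
    out <- array(0, c(Tlen, cfg$d_model, steps))
    for (s in seq_len(steps))
      out[, , s] <- B + ((s - 0.5) / steps) * (X - B)
    out
  }
  grads <- run(stack(Xf, Bx), stack(Xr, Bx))
  avg_f <- apply(grads$dXf, c(1, 2), mean)
  ig_f <- rowSums((Xf - Bx) * avg_f)
  if (cfg$use_pam) {
    avg_r <- apply(grads$dXr, c(1, 2), mean)
    ig_r <- rowSums((Xr - Bx) * avg_r)
  } else ig_r <- rep(0, Tlen)
  # map reverse-branch token attributions back to forward coordinates
  ig_r_mapped <- rep(0, Tlen)
  if (cfg$prepend_cls) {
    ig_r_mapped[1] <- ig_r[1]
    if (Tlen > 1) ig_r_mapped[2:Tlen] <- rev(ig_r[2:Tlen])
  } else {
    ig_r_mapped <- rev(ig_r)
  }
  ends <- run(array(c(Xf, Bx), c(Tlen, cfg$d_model, 2)),
              array(c(Xr, Bx), c(Tlen, cfg$d_model, 2)))
  prediction <- ends$preds[1]
  baseline_prediction <- ends$preds[2]
  ig <- ig_f + ig_r_mapped
  tokens <- c(if (cfg$prepend_cls) "<cls>",
              kmer_tokenize(sequence, model$vocab$k))
  structure(list(probe_id = probe_id %||% NA_character_, tokens = tokens,
                 ig_values = ig, ig_forward = ig_f,
                 ig_reverse_mapped = ig_r_mapped,
                 prediction = prediction,
                 baseline_prediction = baseline_prediction,
                 completeness_gap = prediction - baseline_prediction - sum(ig),
                 steps = steps),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf(paste0("<attribution_result> %s: %d tokens, pred %.4f, ",
                     "baseline %.4f, completeness gap %.2e (%d steps)\n"),
              x$probe_id, length(x$ig_values), x$prediction,
              x$baseline_prediction, x$completeness_gap, x$steps))
  invisible(x)
}

#' Integrated gradients for a set of probes
#'
#' @param model a trained [depth_model()].
#' @param probes a [probe_set()] or character vector.
#' @param ... passed to [integrated_gradients()].
#' @return list of `attribution_result`, one per probe.
#' @export
integrated_gradients_set <- function(model, probes, ...) {
  seqs <- if (inherits(probes, "probe_set")) probes$sequence
          else as.character(probes)
  ids <- if (inherits(probes, "probe_set")) probes$probe_id
         else names(seqs) %||% as.character(seq_along(seqs))
  Map(function(s, id) integrated_gradients(model, s, probe_id = id, ...),
      seqs, ids)
}

#' Position-wise mean absolute attribution profile
#'
#' Averages `|IG|` per token position across probes of identical tokenized
#' length — the plot-ready positional importance profile.
#'
#' @param attributions list of `attribution_result` (same tokenized
#'   length).
#' @return A data frame with `position` (1-based token position), `token`
#'   (`<cls>` or `kmer`), `mean_abs_ig`.
#' @export
positional_importance <- function(attributions) {
  if (length(attributions) == 0) stop("no attributions supplied")
  lens <- vapply(attributions, function(a) length(a$ig_values), integer(1))
  if (length(unique(lens)) != 1)
    stop("attributions have different tokenized lengths; ",
         "group probes by length and call once per group")
  M <- vapply(attributions, function(a) abs(a$ig_values), numeric(lens[1]))
  data.frame(position = seq_len(lens[1]),
             token = ifelse(attributions[[1]]$tokens == "<cls>", "<cls>",
                            "kmer"),
             mean_abs_ig = rowMeans(M))
}

#' Extract extreme-depth probe sets
#'
#' On z-scored (standard-normalized) depths, the high set is probes with
#' `z > qnorm(1 - rate)` and the low set those with `z < qnorm(rate)` —
#' a per-tail Gaussian cut at the given rate.
#'
#' @param normalized_depths numeric vector of z-scored depths, named by
#'   probe_id (names optional).
#' @param rate tail rate in (0, 0.5); default 0.05.
#' @return A list: `high` and `low` (indices, or names when available) and
#'   `thresholds` (`c(low, high)` z cutoffs).
#' @export
extreme_depth_sets <- function(normalized_depths, rate = 0.05) {
  if (rate <= 0 || rate >= 0.5) stop("rate must be in (0, 0.5)")
  hi_thr <- stats::qnorm(1 - rate)
  lo_thr <- stats::qnorm(rate)
  pick <- function(mask) {
    if (!is.null(names(normalized_depths))) names(normalized_depths)[mask]
    else which(mask)
  }
  list(high = pick(normalized_depths > hi_thr),
       low = pick(normalized_depths < lo_thr),
       thresholds = c(low = lo_thr, high = hi_thr))
}

#' k-mer frequency enrichment of a probe subset against a background
#'
#' Frequencies are k-mer counts over total k-mers per group; the ratio is
#' subset over background frequency, guarding empty background cells with
#' a pseudo-frequency of one over the group's total k-mer count.
#'
#' @param subset,background [probe_set()]s or character vectors of
#'   sequences.
#' @param k k-mer size (default 3).
#' @return A data frame sorted by decreasing ratio: `kmer`, `freq_subset`,
#'   `freq_background`, `ratio`.
#' @export
kmer_enrichment <- function(subset, background, k = 3) {
  get_seqs <- function(x) {
    s <- if (inherits(x, "probe_set")) x$sequence else as.character(x)
    if (length(s) == 0) stop("empty probe group")
    s
  }
  count_kmers <- function(seqs) {
    tab <- table(unlist(lapply(seqs, kmer_tokenize, k = k)))
    all_k <- build_vocab(k)$id_to_token[-(1:3)]
    counts <- stats::setNames(numeric(length(all_k)), all_k)
    counts[names(tab)] <- as.numeric(tab)
    counts
  }
  cs <- count_kmers(get_seqs(subset))
  cb <- count_kmers(get_seqs(background))
  fs <- cs / sum(cs)
  fb <- cb / sum(cb)
  ratio <- fs / pmax(fb, 1 / sum(cb))
  out <- data.frame(kmer = names(cs), freq_subset = unname(fs),
                    freq_background = unname(fb), ratio = unname(ratio))
  out[order(-out$ratio), , drop = FALSE]
}

#' Mono- and dinucleotide composition of a probe group
#'
#' Companion to [kmer_enrichment()] for inspecting base-level composition
#' of extreme-depth sets (e.g. C+T content versus CT dinucleotide
#' frequency, two readings of "CT content").
#'
#' @param probes a [probe_set()] or character vector.
#' @return A list with `base` and `dinucleotide` frequency tables (named
#'   numeric vectors summing to 1).
#' @export
sequence_composition <- function(probes) {
  seqs <- if (inherits(probes, "probe_set")) probes$sequence
          else as.character(probes)
  base_counts <- table(unlist(strsplit(seqs, "", fixed = TRUE)))
  di <- table(unlist(lapply(seqs, kmer_tokenize, k = 2)))
  base_f <- sort(stats::setNames(as.numeric(base_counts) / sum(base_counts),
                                 names(base_counts)), decreasing = TRUE)
  di_f <- sort(stats::setNames(as.numeric(di) / sum(di), names(di)),
               decreasing = TRUE)
  list(base = base_f, dinucleotide = di_f)
}

#' Rank correlation between attribution scores and thermodynamic metrics
#'
#' Kendall's tau-b between a per-probe attribution statistic (e.g. summed
#' `|IG|`) and each thermodynamic column of an externally computed table.
#'
#' @param ig_summary named numeric vector: one attribution statistic per
#'   probe_id.
#' @param thermo_table data frame with `probe_id` plus one numeric column
#'   per thermodynamic metric (see [read_thermo_table()]).
#' @return A data frame: `metric`, `kendall_tau`, `n`.
#' @export
thermo_correlation <- function(ig_summary, thermo_table) {
  if (is.null(names(ig_summary))) stop("ig_summary must be named by probe_id")
  common <- intersect(names(ig_summary), thermo_table$probe_id)
  if (length(common) < 10) stop("need >= 10 paired observations")
  x <- ig_summary[common]
  metrics <- setdiff(names(thermo_table), "probe_id")
  rows <- lapply(metrics, function(m) {
    y <- thermo_table[[m]][match(common, thermo_table$probe_id)]
    if (!is.numeric(y)) stop(sprintf("metric '%s' is not numeric", m))
    if (stats::sd(y) == 0)
      stop(sprintf("metric '%s' has all tied values", m))
    data.frame(metric = m,
               kendall_tau = stats::cor(x, y, method = "kendall"),
               n = length(common))
  })
  do.call(rbind, rows)
}

#' Read a thermodynamics table
#'
#' Tab-separated, one row per probe:
#' `probe_id<TAB>free_energy_kcal_per_mol<TAB>structure_stability` (extra
#' numeric columns are carried along).
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_thermo_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"probe_id" %in% names(df))
    stop("thermo table must have a probe_id column")
  df
}

#' Token positions covered by a motif
#'
#' Helper for attribution analyses on synthetic panels: the (1-based)
#' forward token positions whose k-mer window overlaps at least one
#' occurrence of the motif, on the same axis as
#' `attribution_result$ig_values` (i.e. shifted by one when a `<cls>`
#' token is prepended).
#'
#' @param sequence a probe sequence.
#' @param motif motif string.
#' @param k k-mer size of the tokenization.
#' @param prepend_cls whether tokenization prepended `<cls>`.
#' @return integer vector of token positions (possibly empty).
#' @export
motif_token_positions <- function(sequence, motif, k, prepend_cls = TRUE) {
  L <- nchar(sequence)
  m <- nchar(motif)
  starts <- motif_starts(sequence, motif)
  pos <- integer(0)
  for (p in starts) {
    lo <- max(1L, p - k + 1L)
    hi <- min(L - k + 1L, p + m - 1L)
    if (hi >= lo) pos <- c(pos, lo:hi)
  }
  pos <- sort(unique(pos))
  if (prepend_cls) pos + 1L else pos
}
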