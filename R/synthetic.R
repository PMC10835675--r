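# Synthetic probe panels with a known sequence-to-depth law.
#
# The generator is a statistical stand-in for a capture experiment: depths
# vary on the log10 scale as an additive function of sequence composition
# (GC fraction and planted motif occurrences) plus Gaussian noise, so every
# downstream component — training, metrics, cross-validation, attribution —
# can be validated against ground truth at desk scale.

#' Parameters of the synthetic panel generator
#'
#' The log10 depth law is
#' `beta0 + beta_gc * GC(seq) + sum over motifs of effect * weighted count`,
#' with i.i.d. `N(0, noise_sd^2)` log10-scale noise on top.  Motif
#' occurrences are counted with overlaps; under the `"center_weighted"`
#' profile an occurrence's contribution is scaled by a triangular weight
#' that is 1 mid-probe and falls linearly to 0 at the ends, mimicking the
#' empirically higher importance of mid-probe nucleotides.
#'
#' @param n_probes panel size.
#' @param length probe length in nt (all probes equal length).
#' @param beta0 baseline log10 depth.
#' @param beta_gc additive log10 effect per unit GC fraction.
#' @param motif_effects named numeric vector: additive log10 effect per
#'   (weighted) occurrence of each motif.
#' @param positional_profile `"uniform"` or `"center_weighted"`.
#' @param noise_sd log10-scale Gaussian noise standard deviation.
#' @param seed generator seed.
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_probes = 3000, length = 60, beta0 = 2,
                             beta_gc = 0.8, motif_effects = c(CTT = 0.3),
                             positional_profile = c("uniform",
                                                    "center_weighted"),
                             noise_sd = 0.15, seed = 1) {
  positional_profile <- match.arg(positional_profile)
  if (n_probes < 1) stop("n_probes must be >= 1")
  if (length(motif_effects) > 0) {
    if (is.null(names(motif_effects)) || any(!nzchar(names(motif_effects))))
      stop("motif_effects must be named by motif")
    if (any(nchar(names(motif_effects)) > length))
      stop("probe length must cover the longest motif")
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(n_probes = as.integer(n_probes), length = as.integer(length),
                 beta0 = beta0, beta_gc = beta_gc,
                 motif_effects = motif_effects,
                 positional_profile = positional_profile,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Generate i.i.d. uniform-random probe sequences
#'
#' @param params a [synthetic_params()].
#' @return character vector of `n_probes` sequences of the configured
#'   length; deterministic under the configured seed.
#' @export
generate_sequences <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  with_seed(params$seed, {
    m <- matrix(sample(c("A", "C", "G", "T"),
                       params$n_probes * params$length, replace = TRUE),
                params$n_probes, params$length)
    apply(m, 1, paste, collapse = "")
  })
}

gc_fraction <- function(sequences) {
  (nchar(gsub("[^GC]", "", sequences))) / nchar(sequences)
}

# 1-based start positions of (possibly overlapping) motif occurrences.
motif_starts <- function(sequence, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

# Positional weight of an occurrence starting at p (1-based) in a sequence
# of length L for a motif of length m: 1 under the uniform profile, else a
# triangle peaking at the central start position.
motif_weight <- function(p, L, m, profile) {
  if (profile == "uniform") return(rep(1, length(p)))
  n_starts <- L - m + 1
  if (n_starts <= 1) return(rep(1, length(p)))
  center <- (1 + n_starts) / 2
  1 - abs(p - center) / (center - 1)
}

#' Ground-truth log10 depth of sequences under the generator law
#'
#' @param sequence character vector of sequences.
#' @param params a [synthetic_params()].
#' @return numeric vector of noise-free log10 depths.
#' @export
true_log10_depth <- function(sequence, params) {
  stopifnot(inherits(params, "synthetic_params"))
  out <- params$beta0 + params$beta_gc * gc_fraction(sequence)
  for (motif in names(params$motif_effects)) {
    eff <- params$motif_effects[[motif]]
    m <- nchar(motif)
    contrib <- vapply(sequence, function(s) {
      p <- motif_starts(s, motif)
      if (length(p) == 0) return(0)
      sum(motif_weight(p, nchar(s), m, params$positional_profile)) * eff
    }, numeric(1), USE.NAMES = FALSE)
    out <- out + contrib
  }
  out
}

#' Simulate a probe panel with observed depths
#'
#' Observed depth is `10^(true_log10_depth + eps)` with
#' `eps ~ N(0, noise_sd^2)`; the ground-truth table is returned alongside
#' for recovery tests.
#'
#' @param params a [synthetic_params()].
#' @return A list of class `synthetic_panel`: `probes` (a [probe_set()]),
#'   `truth` (data frame `probe_id`, `true_log10_depth`) and `params`.
#' @export
simulate_panel <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  seqs <- generate_sequences(params)
  truth <- true_log10_depth(seqs, params)
  eps <- with_seed(params$seed + 1L,
                   rnorm(params$n_probes, sd = params$noise_sd))
  ids <- sprintf("probe_%05d", seq_len(params$n_probes))
  structure(list(probes = probe_set(ids, seqs, 10^(truth + eps),
                                    panel_name = "synthetic"),
                 truth = data.frame(probe_id = ids, true_log10_depth = truth,
                                    stringsAsFactors = FALSE),
                 params = params),
            class = "synthetic_panel")
}

#' Write a simulated panel to disk
#'
#' Emits `probes.fasta`, `depths.tsv` (the exact formats [read_panel()]
#' consumes) and `truth.tsv`.
#'
#' @param panel a [simulate_panel()] result.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "synthetic_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(panel$probes$sequence)
  names(seqs) <- panel$probes$probe_id
  Biostrings::writeXStringSet(seqs, file.path(dir, "probes.fasta"))
  utils::write.table(
    data.frame(probe_id = panel$probes$probe_id,
               depth = panel$probes$observed_depth),
    file.path(dir, "depths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(panel$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
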