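# Panel input/output: FASTA + depth tables, depth normalization, CV folds.

#' Construct a probe set
#'
#' A probe set is a data frame with columns `probe_id`, `sequence` and
#' `observed_depth`, one row per probe, carrying the panel name as an
#' attribute.  Sequences are restricted to `{A,C,G,T,N}` (uppercased on
#' input) and depths must be nonnegative.
#'
#' @param probe_id character vector of unique, non-empty ids.
#' @param sequence character vector of probe sequences.
#' @param observed_depth numeric vector of raw read depths.
#' @param panel_name optional panel label.
#' @return A data frame of class `probe_set`.
#' @export
probe_set <- function(probe_id, sequence, observed_depth,
                      panel_name = "panel") {
  probe_id <- as.character(probe_id)
  sequence <- toupper(as.character(sequence))
  observed_depth <- as.numeric(observed_depth)
  if (length(probe_id) == 0) stop("probe set is empty")
  if (anyDuplicated(probe_id)) stop("probe_ids must be unique")
  if (any(!nzchar(probe_id))) stop("probe_ids must be non-empty")
  if (any(nchar(sequence) < 1)) stop("sequences must have length >= 1")
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop(sprintf("sequence for probe '%s' contains characters outside {A,C,G,T,N}",
                 probe_id[which(bad)[1]]))
  if (any(is.na(observed_depth) | observed_depth < 0))
    stop("observed depths must be nonnegative numbers")
  out <- data.frame(probe_id = probe_id, sequence = sequence,
                    observed_depth = observed_depth,
                    stringsAsFactors = FALSE)
  attr(out, "panel_name") <- panel_name
  class(out) <- c("probe_set", "data.frame")
  out
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set> '%s': %d probes, length %d-%d nt, depth %.3g-%.3g\n",
              attr(x, "panel_name") %||% "panel", nrow(x),
              min(nchar(x$sequence)), max(nchar(x$sequence)),
              min(x$observed_depth), max(x$observed_depth)))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... and %d more probes\n", nrow(x) - 5))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a probe panel from FASTA plus a depth table
#'
#' The FASTA file supplies the probe sequences (ids taken up to the first
#' whitespace); the depth table is a two-column tab-separated file with
#' header `probe_id<TAB>depth` (lines starting with `#` are ignored).
#' Probes present in both files are returned in FASTA order; FASTA records
#' without a depth are dropped with a warning.
#'
#' @param fasta_path path to the probe FASTA.
#' @param depth_table_path path to the depth TSV.
#' @param panel_name panel label; defaults to the FASTA file name.
#' @return A [probe_set()].
#' @export
read_panel <- function(fasta_path, depth_table_path, panel_name = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(depth_table_path))
    stop("depth table not found: ", depth_table_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  depth <- utils::read.delim(depth_table_path, comment.char = "#",
                             stringsAsFactors = FALSE)
  if (!all(c("probe_id", "depth") %in% names(depth)))
    stop("depth table must have columns 'probe_id' and 'depth'")
  dn <- suppressWarnings(as.numeric(depth$depth))
  if (any(is.na(dn))) {
    i <- which(is.na(dn))[1]
    stop(sprintf("depth table line %d: depth '%s' is not a number",
                 i + 1L, depth$depth[i]))
  }
  if (any(dn < 0)) {
    i <- which(dn < 0)[1]
    stop(sprintf("depth table line %d: negative depth %s for probe '%s'",
                 i + 1L, format(dn[i]), depth$probe_id[i]))
  }
  if (anyDuplicated(depth$probe_id))
    stop("duplicate probe_ids in depth table")
  if (anyDuplicated(ids)) stop("duplicate ids in FASTA")
  keep <- ids %in% depth$probe_id
  if (!any(keep)) stop("no probe ids shared between FASTA and depth table")
  if (any(!keep))
    warning(sprintf("%d probe(s) without depth dropped", sum(!keep)))
  ids <- ids[keep]
  probe_set(ids,
            as.character(seqs[keep]),
            dn[match(ids, depth$probe_id)],
            panel_name = panel_name %||% basename(fasta_path))
}

#' Normalize observed depths to a standard normal on the log10 scale
#'
#' Depths are shifted by a pseudocount, log10-transformed and z-scored with
#' the population standard deviation, so the output has mean 0 and standard
#' deviation exactly 1.  The fitted parameters allow back-transformation of
#' model predictions.
#'
#' @param probes a [probe_set()] (or a numeric vector of raw depths).
#' @param pseudocount nonnegative shift applied before log10; the default 1
#'   keeps zero-depth probes finite.
#' @return A list with `values` (normalized depths, one per probe) and
#'   `params` (class `depth_norm_params`: `pseudocount`, `mean_log10`,
#'   `sd_log10`).
#' @examples
#' normalize_depths(probe_set(c("a","b","c"), c("ACGT","ACGT","ACGA"),
#'                            c(10, 100, 1000)), pseudocount = 0)$values
#' @export
normalize_depths <- function(probes, pseudocount = 1) {
  d <- if (inherits(probes, "probe_set")) probes$observed_depth
       else as.numeric(probes)
  if (length(d) < 2) stop("need at least 2 probes to normalize")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  shifted <- d + pseudocount
  if (any(shifted <= 0))
    stop("depth + pseudocount must be positive for every probe; ",
         "use a positive pseudocount for zero-depth probes")
  x <- log10(shifted)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))   # population sd: z-scores have sd exactly 1
  if (sigma < 1e-12) stop("constant depths: zero variance after log10 transform")
  params <- structure(list(pseudocount = pseudocount, mean_log10 = mu,
                           sd_log10 = sigma),
                      class = "depth_norm_params")
  list(values = (x - mu) / sigma, params = params)
}

#' Map normalized values back to the log10 depth scale
#'
#' Inverse of the z-scoring step of [normalize_depths()]: returns values on
#' the `log10(depth + pseudocount)` scale, where the evaluation metrics are
#' defined.
#'
#' @param values numeric vector of normalized (z-scored) values.
#' @param params a `depth_norm_params` object.
#' @return numeric vector of log10-scale depths.
#' @export
denormalize <- function(values, params) {
  stopifnot(inherits(params, "depth_norm_params"))
  values * params$sd_log10 + params$mean_log10
}

#' Observed depths on the metric scale
#'
#' Convenience accessor: `log10(observed_depth + pseudocount)`.
#'
#' @param probes a [probe_set()].
#' @param params a `depth_norm_params` (its pseudocount is used).
#' @return numeric vector, one value per probe.
#' @export
observed_log10 <- function(probes, params) {
  log10(probes$observed_depth + params$pseudocount)
}

#' Assign probes to cross-validation folds
#'
#' Probes are shuffled with a local RNG seeded by `seed` and cut into
#' `n_folds` contiguous blocks, giving a disjoint, exhaustive partition
#' whose fold sizes differ by at most one.
#'
#' @param probes a [probe_set()].
#' @param n_folds number of folds (>= 2, <= number of probes).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return An integer vector of class `fold_assignment`: fold index in
#'   `[0, n_folds)` named by probe_id, with attributes `n_folds` and `seed`.
#' @export
make_cv_folds <- function(probes, n_folds, seed = 1) {
  n <- nrow(probes)
  if (n_folds < 2 || n_folds > n)
    stop("n_folds must be between 2 and the number of probes")
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- integer(n)
  fold[perm] <- rep(seq_len(n_folds) - 1L, times = sizes)
  structure(stats::setNames(fold, probes$probe_id),
            n_folds = as.integer(n_folds), seed = as.integer(seed),
            class = "fold_assignment")
}
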