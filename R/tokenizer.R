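# k-mer tokenization of probe sequences, both strands.

PAD_ID <- 0L
UNK_ID <- 1L
CLS_ID <- 2L

#' Build a k-mer vocabulary
#'
#' The vocabulary holds the `4^k` nucleotide k-mers in lexicographic order,
#' preceded by three special tokens: `<pad>` (id 0, batch padding), `<unk>`
#' (id 1, k-mers containing ambiguous bases) and `<cls>` (id 2, the pooled
#' summary position prepended to every tokenized strand).
#'
#' @param k k-mer size, between 1 and 8.
#' @return An object of class `kmer_vocab`: a list with elements `k`,
#'   `id_to_token` (character vector in id order) and `token_to_id`
#'   (named integer vector of 0-based ids).
#' @examples
#' v <- build_vocab(3)
#' length(v$id_to_token)  # 64 k-mers + 3 specials
#' @export
build_vocab <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k != as.integer(k) || k < 1 || k > 8)
    stop("k must be a single integer in [1, 8]")
  k <- as.integer(k)
  kmers <- c("A", "C", "G", "T")
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      # row-major traversal keeps lexicographic order as suffixes grow
      kmers <- as.vector(t(outer(kmers, c("A", "C", "G", "T"), paste0)))
    }
  }
  id_to_token <- c("<pad>", "<unk>", "<cls>", kmers)
  token_to_id <- stats::setNames(seq_along(id_to_token) - 1L, id_to_token)
  structure(list(k = k, id_to_token = id_to_token, token_to_id = token_to_id),
            class = "kmer_vocab")
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("<kmer_vocab> k=%d, %d tokens (%d k-mers + 3 specials)\n",
              x$k, length(x$id_to_token), length(x$id_to_token) - 3L))
  invisible(x)
}

#' Reverse complement of nucleotide sequences
#'
#' Vectorized over sequences; `N` maps to `N`.
#'
#' @param sequence character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(sequence) {
  if (!is.character(sequence)) stop("sequence must be character")
  bad <- regexpr("[^ACGTN]", sequence)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("invalid character '%s' at position %d of sequence %d",
                 substr(sequence[i], bad[i], bad[i]), bad[i], i))
  }
  comp <- chartr("ACGTN", "TGCAN", sequence)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Tokenize a sequence into overlapping k-mers
#'
#' Slides a window of width `k` with stride one across the sequence,
#' yielding `L - k + 1` tokens for a sequence of length `L`.
#'
#' @param sequence a single nucleotide sequence.
#' @param k k-mer size; must not exceed the sequence length.
#' @return character vector of k-mers.
#' @examples
#' kmer_tokenize("ACGTA", 3)  # "ACG" "CGT" "GTA"
#' @export
kmer_tokenize <- function(sequence, k) {
  if (length(sequence) != 1) stop("kmer_tokenize expects a single sequence")
  L <- nchar(sequence)
  if (L < k) stop(sprintf("sequence length %d is shorter than k = %d", L, k))
  starts <- seq_len(L - k + 1)
  substring(sequence, starts, starts + k - 1)
}

#' Encode a probe into token ids for both strands
#'
#' Tokenizes the forward strand and its reverse complement with the
#' vocabulary's k and maps tokens to 0-based ids.  K-mers containing `N`
#' map to the `<unk>` id.  When `prepend_cls` is `TRUE` a `<cls>` id is
#' prepended to both strands; its output position is what first-token
#' pooling reads.
#'
#' @param sequence a single nucleotide sequence.
#' @param vocab a [build_vocab()] vocabulary.
#' @param prepend_cls prepend the `<cls>` token to both strands?
#' @return A list of class `tokenized_pair`: `forward_ids`, `reverse_ids`
#'   (0-based integer vectors of equal length) and `seq_length`.
#' @export
encode_pair <- function(sequence, vocab, prepend_cls = TRUE) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  fwd_tok <- kmer_tokenize(sequence, vocab$k)
  rev_tok <- kmer_tokenize(reverse_complement(sequence), vocab$k)
  to_ids <- function(tok) {
    ids <- unname(vocab$token_to_id[tok])
    ids[is.na(ids)] <- UNK_ID
    if (prepend_cls) ids <- c(CLS_ID, ids)
    as.integer(ids)
  }
  structure(list(forward_ids = to_ids(fwd_tok), reverse_ids = to_ids(rev_tok),
                 seq_length = nchar(sequence)),
            class = "tokenized_pair")
}

#' Reconstruct a sequence from overlapping k-mer tokens
#'
#' Inverse of [kmer_tokenize()]: the first token contributes all k bases,
#' every later token its final base.
#'
#' @param tokens character vector of overlapping k-mers.
#' @return the merged sequence.
#' @export
merge_tokens <- function(tokens) {
  if (length(tokens) == 0) stop("no tokens to merge")
  k <- nchar(tokens[1])
  paste0(tokens[1], paste(substr(tokens[-1], k, k), collapse = ""))
}

#' Write / read a vocabulary as a two-column text file
#'
#' Plain `token<TAB>id` rows, loadable without the package that wrote it.
#'
#' @param vocab a `kmer_vocab`.
#' @param path file path.
#' @return `write_vocab` returns `path` invisibly; `read_vocab` returns the
#'   reconstructed `kmer_vocab`.
#' @export
write_vocab <- function(vocab, path) {
  df <- data.frame(token = vocab$id_to_token,
                   id = seq_along(vocab$id_to_token) - 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- df[order(df$id), ]
  k <- nchar(df$token[df$id == 3L])   # first k-mer after the 3 specials
  v <- build_vocab(k)
  if (!identical(v$id_to_token, df$token))
    stop("vocabulary file does not match a canonical k-mer vocabulary")
  v
}

# Encode many probes into padded id matrices for the compiled core.
# Returns 0-based id matrices (n x max_len) padded with PAD_ID plus lengths.
encode_panel <- function(sequences, vocab, prepend_cls = TRUE) {
  pairs <- lapply(sequences, encode_pair, vocab = vocab,
                  prepend_cls = prepend_cls)
  lens <- vapply(pairs, function(p) length(p$forward_ids), integer(1))
  Tm <- max(lens)
  n <- length(pairs)
  fwd <- matrix(PAD_ID, n, Tm)
  rev <- matrix(PAD_ID, n, Tm)
  for (i in seq_len(n)) {
    fwd[i, seq_len(lens[i])] <- pairs[[i]]$forward_ids
    rev[i, seq_len(lens[i])] <- pairs[[i]]$reverse_ids
  }
  list(fwd = fwd, rev = rev, lens = lens)
}
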