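# Bidirectional k-mer tokenization, skip-gram k-mer embeddings, pooled
# sequence vectors, and the k-mer frequency-vector (KFV) baseline.
#
# "Reverse direction" means the reverse-complement orientation
# (biological convention); plain string reversal is available via
# `reverse = "string"` since either reading is defensible.

#' Reverse-complement DNA sequences
#'
#' @param x Character vector over the strict alphabet ACGT.
#' @return Reverse-complemented sequences. An involution:
#'   `revcomp(revcomp(x)) == x`.
#' @export
revcomp <- function(x) {
  if (!all(grepl("^[ACGT]+$", x)))
    stop("revcomp requires sequences over {A,C,G,T}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

reverse_orientation <- function(x, mode = c("revcomp", "string")) {
  mode <- match.arg(mode)
  if (mode == "revcomp") revcomp(x)
  else vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Tokenize a sequence into bidirectional k-mers
#'
#' Slides a window of length `k` with stride `stride` along the sequence
#' as given (forward tokens) and along its reverse-complement (reverse
#' tokens). Each direction yields `floor((len - k)/stride) + 1` tokens.
#'
#' @param sequence A single ACGT string of length >= `k`.
#' @param k Window length (1..15).
#' @param stride Step between windows (default 1).
#' @param reverse `"revcomp"` (default) or `"string"` for plain reversal.
#' @return A list of class `bikmer_tokens` with elements `k`, `stride`,
#'   `forward`, `reverse`.
#' @examples
#' tokenize_bikmer("ACGTA", k = 3)
#' @export
tokenize_bikmer <- function(sequence, k, stride = 1L,
                            reverse = c("revcomp", "string")) {
  reverse <- match.arg(reverse)
  stopifnot(length(sequence) == 1L, k >= 1L, stride >= 1L)
  if (nchar(sequence) < k)
    stop("sequence of length ", nchar(sequence), " is shorter than k = ", k)
  if (!grepl("^[ACGT]+$", sequence))
    stop("sequence contains non-ACGT characters")
  if (reverse == "revcomp") {
    codes <- .tokenize_codes_cpp(sequence, as.integer(k), as.integer(stride))
    fwd <- .codes_to_kmers_cpp(codes$forward[[1]], as.integer(k))
    rev_ <- .codes_to_kmers_cpp(codes$reverse[[1]], as.integer(k))
  } else {
    codes <- .tokenize_codes_cpp(c(sequence,
                                   reverse_orientation(sequence, "string")),
                                 as.integer(k), as.integer(stride))
    fwd <- .codes_to_kmers_cpp(codes$forward[[1]], as.integer(k))
    rev_ <- .codes_to_kmers_cpp(codes$forward[[2]], as.integer(k))
  }
  structure(list(k = as.integer(k), stride = as.integer(stride),
                 forward = fwd, reverse = rev_),
            class = "bikmer_tokens")
}

#' Build a k-mer sentence corpus from a dataset
#'
#' Each record contributes two sentences — its forward k-mer list, then
#' its reverse-orientation k-mer list — in dataset order.
#'
#' @param dataset A curated `hftc_dataset` (strict ACGT sequences).
#' @param k Window length.
#' @param stride Step between windows.
#' @return A list of character vectors (2 sentences per record).
#' @export
build_corpus <- function(dataset, k, stride = 1L) {
  codes <- .tokenize_codes_cpp(dataset$sequence, as.integer(k),
                               as.integer(stride))
  out <- vector("list", 2L * nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    out[[2L * i - 1L]] <- .codes_to_kmers_cpp(codes$forward[[i]],
                                              as.integer(k))
    out[[2L * i]] <- .codes_to_kmers_cpp(codes$reverse[[i]], as.integer(k))
  }
  out
}

#' Train a skip-gram k-mer embedding
#'
#' Skip-gram with negative sampling over the sentence corpus, trained
#' single-threaded so results are fully reproducible for a fixed seed.
#' The vocabulary is every token with frequency >= `min_count`, ordered
#' by decreasing frequency (ties broken alphabetically).
#'
#' @param corpus List of character token vectors as from [build_corpus()].
#' @param N Embedding dimension per direction (default 100, giving
#'   2N = 200-dimensional sequence vectors).
#' @param window Context window half-width.
#' @param epochs Training epochs.
#' @param negative Negative samples per positive pair.
#' @param min_count Minimum token frequency for vocabulary inclusion.
#' @param seed Integer seed.
#' @param alpha,min_alpha Initial and floor learning rates (word2vec
#'   defaults).
#' @return A `kmer_embedding` object: `k`, `dim`, `vectors` (vocabulary x
#'   N matrix with k-mer rownames), `params`.
#' @export
train_embedding <- function(corpus, N = 100L, window = 5L, epochs = 5L,
                            negative = 5L, min_count = 1L, seed = 1L,
                            alpha = 0.025, min_alpha = 1e-4) {
  if (length(corpus) == 0L || sum(lengths(corpus)) == 0L)
    stop("empty corpus")
  tokens <- unlist(corpus, use.names = FALSE)
  freq <- table(tokens)
  freq <- freq[freq >= min_count]
  if (length(freq) == 0L) stop("no token reaches min_count")
  ord <- order(-as.integer(freq), names(freq))
  vocab <- names(freq)[ord]
  counts <- as.numeric(freq)[ord]
  k <- nchar(vocab[1L])
  idx <- setNames(seq_along(vocab) - 1L, vocab)
  sentences <- lapply(corpus, function(s) {
    m <- idx[s]
    as.integer(m[!is.na(m)])
  })
  sentences <- sentences[lengths(sentences) > 0L]
  mat <- .train_sgns_cpp(sentences, counts, as.integer(N),
                         as.integer(window), as.integer(negative),
                         as.integer(epochs), alpha, min_alpha,
                         as.integer(seed))
  rownames(mat) <- vocab
  structure(list(k = as.integer(k), dim = as.integer(N), vectors = mat,
                 params = list(window = as.integer(window),
                               epochs = as.integer(epochs),
                               negative = as.integer(negative),
                               min_count = as.integer(min_count),
                               seed = as.integer(seed), alpha = alpha,
                               min_alpha = min_alpha)),
            class = "kmer_embedding")
}

#' @export
print.kmer_embedding <- function(x, ...) {
  cat(sprintf("<kmer_embedding> k = %d, dim = %d, vocabulary %d/%d k-mers\n",
              x$k, x$dim, nrow(x$vectors), 4^x$k))
  invisible(x)
}

#' Pool tokenized k-mers into a fixed-length sequence vector
#'
#' The forward half is the arithmetic mean of the embedding vectors of
#' the in-vocabulary forward tokens; the reverse half likewise; the two
#' halves are concatenated to a 2N vector. Out-of-vocabulary tokens are
#' dropped and counted; a direction with no in-vocabulary token
#' contributes an all-zero half.
#'
#' @param tokenized A `bikmer_tokens` object (same `k` as the model).
#' @param model A `kmer_embedding`.
#' @return List of class `hftc_seqvec`: `values` (length 2N), `k`,
#'   `n_oov_forward`, `n_oov_reverse`.
#' @export
embed_sequence <- function(tokenized, model) {
  if (tokenized$k != model$k)
    stop("tokenized k = ", tokenized$k, " does not match model k = ", model$k)
  half <- function(tokens) {
    ix <- match(tokens, rownames(model$vectors))
    oov <- sum(is.na(ix))
    ix <- ix[!is.na(ix)]
    v <- if (length(ix)) colMeans(model$vectors[ix, , drop = FALSE])
         else numeric(model$dim)
    list(v = v, oov = oov)
  }
  f <- half(tokenized$forward)
  r <- half(tokenized$reverse)
  structure(list(values = c(f$v, r$v), k = model$k,
                 n_oov_forward = f$oov, n_oov_reverse = r$oov),
            class = "hftc_seqvec")
}

# Batch embedding: n x 2N matrix for all dataset records (fast path used
# by model training and prediction).
embed_dataset <- function(dataset, model, stride = 1L) {
  n <- nrow(dataset)
  out <- matrix(0, n, 2L * model$dim)
  if (n == 0L) return(out)
  codes <- .tokenize_codes_cpp(dataset$sequence, model$k, as.integer(stride))
  vocab_codes <- kmer_to_code(rownames(model$vectors), model$k)
  lookup <- function(cd) {
    ix <- match(cd, vocab_codes)
    ix <- ix[!is.na(ix)]
    if (length(ix)) colMeans(model$vectors[ix, , drop = FALSE])
    else numeric(model$dim)
  }
  for (i in seq_len(n)) {
    out[i, seq_len(model$dim)] <- lookup(codes$forward[[i]])
    out[i, model$dim + seq_len(model$dim)] <- lookup(codes$reverse[[i]])
  }
  out
}

# integer code of each k-mer string (lexicographic, A<C<G<T)
kmer_to_code <- function(kmers, k) {
  if (length(kmers) == 0L) return(integer())
  m <- matrix(match(unlist(strsplit(kmers, "")), BASES) - 1L,
              ncol = k, byrow = TRUE)
  as.integer(m %*% 4^((k - 1L):0))
}

#' Concatenate sequence vectors across several k values
#'
#' Embeds one sequence with each model (pairwise distinct `k`) and
#' concatenates the 2N vectors in ascending-k order, supporting hybrid
#' k strategies such as 7+8 or 10+7.
#'
#' @param sequence A single ACGT string.
#' @param models List of `kmer_embedding` objects with distinct `k`.
#' @param stride Step between windows.
#' @return Numeric vector of length `2N * length(models)`.
#' @export
embed_multi_k <- function(sequence, models, stride = 1L) {
  ks <- vapply(models, function(m) m$k, integer(1))
  if (anyDuplicated(ks)) stop("models must have pairwise distinct k")
  models <- models[order(ks)]
  unlist(lapply(models, function(m)
    embed_sequence(tokenize_bikmer(sequence, m$k, stride), m)$values))
}

#' k-mer frequency vector (KFV) of a sequence
#'
#' The classical 4^k-dimensional representation used as a baseline for
#' the embeddings: forward-orientation window counts indexed in
#' lexicographic k-mer order (A < C < G < T).
#'
#' @param sequence A single ACGT string of length >= `k`.
#' @param k Window length (1..12; the vector has 4^k entries).
#' @param normalize Divide counts by the number of windows.
#' @param stride Step between windows (default 1).
#' @return List of class `kfv`: `k`, `counts` (length 4^k), `normalized`.
#' @export
kfv <- function(sequence, k, normalize = FALSE, stride = 1L) {
  stopifnot(length(sequence) == 1L)
  if (nchar(sequence) < k)
    stop("sequence of length ", nchar(sequence), " is shorter than k = ", k)
  counts <- .kfv_counts_cpp(sequence, as.integer(k), as.integer(stride))
  vals <- if (normalize) counts / sum(counts) else counts
  structure(list(k = as.integer(k), counts = vals,
                 normalized = isTRUE(normalize)), class = "kfv")
}

#' Write an embedding in word2vec text format
#'
#' First line `"<vocab_size> <dim>"`, then one `"token v1 ... vN"` row
#' per k-mer.
#'
#' @param model A `kmer_embedding`.
#' @param path Output path.
#' @export
write_embedding <- function(model, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(model$vectors), model$dim), con)
  rows <- apply(model$vectors, 1L, function(v)
    paste(sprintf("%.9g", v), collapse = " "))
  writeLines(paste(rownames(model$vectors), rows), con)
  invisible(path)
}

#' Read an embedding from word2vec text format
#'
#' @param path Path to a file written by [write_embedding()].
#' @param params Optional training-parameter list to attach.
#' @return A `kmer_embedding`.
#' @export
read_embedding <- function(path, params = list()) {
  lines <- readLines(path)
  hd <- as.integer(strsplit(lines[1L], " ")[[1]])
  parts <- strsplit(lines[-1L], " ", fixed = TRUE)
  vocab <- vapply(parts, `[`, "", 1L)
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  if (is.null(mat)) mat <- matrix(numeric(), 0L, hd[2L])
  rownames(mat) <- vocab
  stopifnot(nrow(mat) == hd[1L], ncol(mat) == hd[2L])
  structure(list(k = nchar(vocab[1L]), dim = hd[2L], vectors = mat,
                 params = params),
            class = "kmer_embedding")
}
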