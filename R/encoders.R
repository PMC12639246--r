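#' Column-wise max pooling of a residue embedding matrix
#'
#' Collapses an `L x d` per-residue embedding matrix into a single
#' `d`-vector by taking the maximum over residues in each embedding
#' dimension. Permutation-invariant in the residue order.
#'
#' @param embeddings numeric matrix, rows = residues, columns = embedding
#'   dimensions; must have at least one row.
#' @return numeric vector of length `ncol(embeddings)`.
#' @export
pool_max <- function(embeddings) {
  if (!is.matrix(embeddings) || nrow(embeddings) < 1L)
    stop("embeddings must be a matrix with at least one row")
  idx <- max.col(t(embeddings), ties.method = "first")
  embeddings[cbind(idx, seq_len(ncol(embeddings)))]
}

# max pooling that also returns the argmax row per column, for backprop
pool_max_with_argmax <- function(embeddings) {
  idx <- max.col(t(embeddings), ties.method = "first")
  list(value = embeddings[cbind(idx, seq_len(ncol(embeddings)))], argmax = idx)
}

#' Hadamard fusion of two pooled embeddings
#'
#' Elementwise product of two equal-length vectors; the commutative fusion
#' that makes the Siamese prediction invariant to argument order.
#'
#' @param u,v numeric vectors of equal length.
#' @return numeric vector `u * v`.
#' @export
fuse_hadamard <- function(u, v) {
  if (length(u) != length(v))
    stop(sprintf("dimension mismatch in Hadamard fusion: %d vs %d",
                 length(u), length(v)))
  u * v
}

#' Tiny trainable per-residue encoder
#'
#' A deliberately small position-aware encoder for desk-scale training: each
#' residue's embedding is the elementwise product of a trainable
#' residue-type embedding (21 codes: the 20 amino acids plus unknown) and a
#' trainable positional scaling vector. It fills the same contract as a
#' large protein language model (sequence of length L in, `L x d` matrix of
#' finite values out, deterministic for fixed weights) at a fraction of the
#' size, and is fine-tuned jointly with the regression head.
#'
#' @param embed_dim embedding dimension `d`.
#' @param max_len maximum sequence length the positional table covers.
#' @param seed RNG seed for weight initialization.
#' @return a `pairbind_encoder` object with `mode = "trainable"` and
#'   Hadamard fusion.
#' @export
tiny_encoder <- function(embed_dim = 32, max_len = 512, seed = 1) {
  params <- withr_seed(seed, list(
    E = matrix(rnorm(21 * embed_dim, sd = 0.5), 21, embed_dim),
    S = matrix(1 + rnorm(max_len * embed_dim, sd = 0.2), max_len, embed_dim)))
  structure(list(name = "tiny", embed_dim = embed_dim, max_len = max_len,
                 mode = "trainable", fusion = "hadamard", params = params),
            class = "pairbind_encoder")
}

#' Frozen bidirectional LSTM encoder (baseline)
#'
#' Runs a bidirectional LSTM with a fixed (seeded, untrained) random
#' recurrent core over the sequence and returns the concatenated final
#' hidden states of the two directions as the sequence encoding. Only the
#' regression head is trained on top (`mode = "frozen"`). The two chain
#' encodings are fused by concatenation, not Hadamard product, so this
#' baseline is not invariant to argument order. Its positional bias toward
#' early residues is mitigated at inference time by overlapping-chunk
#' averaging (see [chunked_predict()]).
#'
#' @param hidden latent dimension per direction.
#' @param embed_dim dimension of the fixed residue input embedding.
#' @param max_len maximum sequence length accepted.
#' @param seed RNG seed for the frozen weights.
#' @return a `pairbind_encoder` object with `mode = "frozen"` and
#'   concatenation fusion; the pair feature has length `4 * hidden`.
#' @export
bilstm_encoder <- function(hidden = 10, embed_dim = 8, max_len = 2000, seed = 1) {
  dir_params <- function() list(
    Wx = matrix(rnorm(embed_dim * 4 * hidden, sd = 0.5), embed_dim, 4 * hidden),
    Wh = matrix(rnorm(hidden * 4 * hidden, sd = 0.5), hidden, 4 * hidden),
    b = rnorm(4 * hidden, sd = 0.1))
  params <- withr_seed(seed, list(
    Wemb = matrix(rnorm(21 * embed_dim, sd = 0.5), 21, embed_dim),
    fwd = dir_params(), bwd = dir_params(), hidden = hidden))
  structure(list(name = "bilstm", embed_dim = 2 * hidden, max_len = max_len,
                 mode = "frozen", fusion = "concat", params = params),
            class = "pairbind_encoder")
}

#' Adapter for externally precomputed per-residue embeddings
#'
#' Wraps a table of precomputed `L x d` embedding matrices (for example
#' exported from a large protein language model run elsewhere) keyed by
#' sequence string or sequence id, so heavyweight encoders can be used
#' offline. The encoder is frozen; only the head is trained.
#'
#' @param embeddings named list of numeric matrices; names are the exact
#'   sequences (or ids supplied at predict time).
#' @param embed_dim embedding dimension; inferred from the first matrix when
#'   missing.
#' @return a `pairbind_encoder` with `mode = "frozen"` and Hadamard fusion.
#' @export
precomputed_encoder <- function(embeddings, embed_dim = NULL) {
  stopifnot(is.list(embeddings), length(embeddings) >= 1,
            !is.null(names(embeddings)))
  if (is.null(embed_dim)) embed_dim <- ncol(embeddings[[1]])
  ok <- vapply(embeddings, function(m)
    is.matrix(m) && ncol(m) == embed_dim && all(is.finite(m)), logical(1))
  if (!all(ok)) stop("all embeddings must be finite matrices with ", embed_dim, " columns")
  structure(list(name = "precomputed", embed_dim = embed_dim, max_len = NULL,
                 mode = "frozen", fusion = "hadamard", params = list(tab = embeddings)),
            class = "pairbind_encoder")
}

#' @export
print.pairbind_encoder <- function(x, ...) {
  cat(sprintf("<encoder '%s': d=%d, mode=%s, fusion=%s>\n",
              x$name, x$embed_dim, x$mode, x$fusion))
  invisible(x)
}

# per-residue embedding matrix for the tiny encoder
tiny_embed <- function(params, ints) {
  L <- length(ints)
  params$E[ints, , drop = FALSE] * params$S[seq_len(L), , drop = FALSE]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# one-directional LSTM pass; returns the final hidden state
lstm_last_hidden <- function(x_emb, w, hidden) {
  h <- numeric(hidden); cc <- numeric(hidden)
  hi <- seq_len(hidden)
  for (t in seq_len(nrow(x_emb))) {
    z <- drop(x_emb[t, ] %*% w$Wx) + drop(h %*% w$Wh) + w$b
    i <- sigmoid(z[hi]); f <- sigmoid(z[hi + hidden])
    g <- tanh(z[hi + 2L * hidden]); o <- sigmoid(z[hi + 3L * hidden])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
  }
  h
}

# BiLSTM sequence encoding: c(final forward hidden, final backward hidden)
bilstm_encode <- function(params, ints) {
  x <- params$Wemb[ints, , drop = FALSE]
  c(lstm_last_hidden(x, params$fwd, params$hidden),
    lstm_last_hidden(x[rev(seq_len(nrow(x))), , drop = FALSE],
                     params$bwd, params$hidden))
}
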