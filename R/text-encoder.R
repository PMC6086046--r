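#' Build a word-embedding vocabulary from resolved class texts
#'
#' Collects every token occurring in the vertex texts plus a shared
#' `<unk>` entry used for out-of-vocabulary tokens at inference time.
#'
#' @param texts Character vector of normalized (space-separated, lowercase)
#'   texts.
#' @return Character vector of vocabulary tokens, sorted, with `"<unk>"`
#'   appended last.
#' @export
build_vocab <- function(texts) {
  toks <- unique(unlist(strsplit(texts, " ", fixed = TRUE)))
  toks <- sort(toks[nzchar(toks)])
  c(toks, "<unk>")
}

tokens_to_ids <- function(text, vocab, max_len = 100L) {
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  toks <- head(toks[nzchar(toks)], max_len)
  ids <- match(toks, vocab)
  ids[is.na(ids)] <- length(vocab)  # <unk>
  ids
}

#' Convolve a token sequence over a sliding window
#'
#' Single-layer convolution of the word-embedding sequence: for each window
#' position the stacked window of word vectors is multiplied by the filter
#' bank and offset by a bias. The output is linear (no nonlinearity): the
#' only squashing in the text encoder is the `tanh` inside the mutual
#' attention correlation. Sequences shorter than the window are zero-padded
#' to window length, so the output always has at least one column.
#'
#' @param E A `d x L` matrix of word vectors (one column per token).
#' @param W A `d_out x (window*d)` filter matrix.
#' @param b Length-`d_out` bias vector.
#' @param window Window width (default 3).
#' @return A list with `U` (`d_out x m` output, `m = max(L, window) -
#'   window + 1`) and the im2col matrix `X` used for backpropagation.
#' @export
convolve_text <- function(E, W, b, window = 3L) {
  stopifnot(is.matrix(E), nrow(E) >= 1L, ncol(E) >= 1L, window >= 1L)
  d <- nrow(E)
  L <- ncol(E)
  if (L < window) {
    E <- cbind(E, matrix(0, d, window - L))
  }
  Lp <- ncol(E)
  m <- Lp - window + 1L
  X <- matrix(0, window * d, m)
  for (t in seq_len(m)) {
    X[, t] <- as.vector(E[, t:(t + window - 1L)])
  }
  U <- W %*% X + b
  list(U = U, X = X, L = L, window = window, d = d)
}

#' Mutual attention between two convolution outputs
#'
#' Computes the correlation matrix `C = tanh(t(U) %*% A %*% V)` between the
#' convolved texts of two vertices, mean-pools its rows and columns into
#' importance scores, and softmaxes those into a pair of attention vectors.
#' The attentive matrix `A` is trainable and lets each vertex emphasise the
#' words its neighbour attends to.
#'
#' @param U,V Convolution outputs (`d x m` and `d x n`).
#' @param A The `d x d` attentive matrix.
#' @return A list with `C` (the `m x n` correlation matrix), importance
#'   scores `h_u`, `h_v`, and attention vectors `a_u`, `a_v` (each
#'   non-negative, summing to 1).
#' @export
mutual_attention <- function(U, V, A) {
  if (nrow(U) != nrow(A) || nrow(V) != ncol(A)) {
    abort(sprintf("mutual_attention: non-conformable shapes (U %dx%d, A %dx%d, V %dx%d)",
                  nrow(U), ncol(U), nrow(A), ncol(A), nrow(V), ncol(V)),
          class = "ontropy_shape_error")
  }
  M <- crossprod(U, A %*% V)
  C <- tanh(M)
  h_u <- rowMeans(C)
  h_v <- colMeans(C)
  list(C = C, h_u = h_u, h_v = h_v,
       a_u = softmax(h_u), a_v = softmax(h_v))
}

#' Attention-weighted pooling of convolution columns
#'
#' `pool_text(U, a)` returns `U %*% a`: the attention-weighted combination
#' of the convolved positions, producing one text vector of length `d`.
#'
#' @param U A `d x m` convolution output.
#' @param a A length-`m` attention vector summing to 1.
#' @return A numeric vector of length `d`.
#' @export
pool_text <- function(U, a) {
  stopifnot(ncol(U) == length(a))
  as.vector(U %*% a)
}

## ---- paired forward/backward used by training ---------------------------

# Forward pass for an ordered vertex pair (i, j): convolve both texts, run
# mutual attention, pool. Returns both context vectors and a cache for
# backpropagation. Token ids are integer indices into the word table.
text_pair_forward <- function(ids_i, ids_j, Wword, Wconv, bconv, A, window) {
  Ei <- t(Wword[ids_i, , drop = FALSE])
  Ej <- t(Wword[ids_j, , drop = FALSE])
  ci <- convolve_text(Ei, Wconv, bconv, window)
  cj <- convolve_text(Ej, Wconv, bconv, window)
  att <- mutual_attention(ci$U, cj$U, A)
  list(
    u_t = pool_text(ci$U, att$a_u),
    v_t = pool_text(cj$U, att$a_v),
    ci = ci, cj = cj, att = att,
    ids_i = ids_i, ids_j = ids_j
  )
}

# Backward pass: given gradients g_u on u_t and g_v on v_t, accumulate
# gradients for the word table, convolution filters/bias and attentive
# matrix into the environment `acc` (fields gW, gWc, gb, gA).
text_pair_backward <- function(cache, g_u, g_v, Wconv, A, window, acc) {
  U <- cache$ci$U; V <- cache$cj$U
  a_u <- cache$att$a_u; a_v <- cache$att$a_v
  C <- cache$att$C
  m <- ncol(U); n <- ncol(V)

  gU <- outer(g_u, a_u)
  gV <- outer(g_v, a_v)
  ga_u <- as.vector(crossprod(U, g_u))
  ga_v <- as.vector(crossprod(V, g_v))
  gh_u <- a_u * (ga_u - sum(ga_u * a_u))
  gh_v <- a_v * (ga_v - sum(ga_v * a_v))
  gC <- outer(gh_u, rep(1 / n, n)) + outer(rep(1 / m, m), gh_v)
  gM <- gC * (1 - C^2)
  acc$gA <- acc$gA + U %*% gM %*% t(V)
  gU <- gU + A %*% V %*% t(gM)
  gV <- gV + t(A) %*% U %*% gM

  backprop_conv <- function(gOut, conv, ids) {
    acc$gWc <- acc$gWc + gOut %*% t(conv$X)
    acc$gb <- acc$gb + rowSums(gOut)
    gX <- crossprod(Wconv, gOut)
    d <- conv$d; w <- conv$window
    Lp <- ncol(conv$X) + w - 1L
    gE <- matrix(0, d, Lp)
    for (t in seq_len(ncol(gX))) {
      gE[, t:(t + w - 1L)] <- gE[, t:(t + w - 1L)] + matrix(gX[, t], d, w)
    }
    for (k in seq_along(ids)) {       # padded columns (> length(ids)) are fixed zeros
      acc$gW[ids[k], ] <- acc$gW[ids[k], ] + gE[, k]
    }
  }
  backprop_conv(gU, cache$ci, cache$ids_i)
  backprop_conv(gV, cache$cj, cache$ids_j)
  invisible(NULL)
}
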