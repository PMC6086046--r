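#' Configuration for joint structure/text embedding training
#'
#' Collects every hyperparameter of the joint objective. Structure and text
#' embeddings share one width `dim` because the cross-space terms of the
#' objective (`log p(v_s | u_t)` and `log p(v_t | u_s)`) dot text vectors
#' with structure vectors directly.
#'
#' @param dim Shared embedding width for structure vectors, word vectors and
#'   text vectors (default 32).
#' @param conv_window Convolution window over the token sequence (default 3).
#' @param max_text_len Texts are truncated to this many tokens (default 100).
#' @param alpha,beta,gamma Weights of the text-text, text-structure and
#'   structure-text terms of the per-edge objective. The structure-structure
#'   term always has weight 1.
#' @param epochs Training epochs (full passes over the edge set).
#' @param learning_rate Initial SGD step size; decays linearly to a tenth of
#'   its value over training.
#' @param negatives Negative samples per edge and term.
#' @param walk_length,walks_per_vertex,walk_window,return_param,inout_param
#'   Random-walk corpus parameters (see [generate_walks()]).
#' @param walk_pairs_per_epoch Number of skip-gram walk pairs used for
#'   structure-only updates each epoch; `NULL` means 5 times the edge count.
#' @param use_walks Whether to include walk-pair structure updates.
#' @param exact_softmax_cutoff Exact softmax (over all vertices) is allowed
#'   in [structure_loss()]/[edge_objective()] only up to this vertex count.
#' @param seed Integer seed controlling initialization and all sampling.
#' @return A list of class `joint_config`.
#' @export
joint_config <- function(dim = 32L, conv_window = 3L, max_text_len = 100L,
                         alpha = 1, beta = 0.3, gamma = 0.3,
                         epochs = 10L, learning_rate = 0.025, negatives = 5L,
                         walk_length = 40L, walks_per_vertex = 10L,
                         walk_window = 5L, return_param = 1, inout_param = 1,
                         walk_pairs_per_epoch = NULL, use_walks = TRUE,
                         exact_softmax_cutoff = 200L, seed = 1L) {
  stopifnot(dim >= 1L, alpha >= 0, beta >= 0, gamma >= 0, epochs >= 0L,
            negatives >= 1L, learning_rate >= 0)
  structure(as.list(environment()), class = "joint_config")
}

#' Train joint structure and text embeddings on a class graph
#'
#' Maximizes, by stochastic gradient ascent over shuffled edges, the summed
#' per-edge objective `L_s + alpha L_tt + beta L_ts + gamma L_st`, where
#' each term is a negative-sampled log conditional probability of softmax
#' form: `L_s` conditions structure on structure, `L_tt` text on text,
#' `L_ts` text on structure and `L_st` structure on text, so that both
#' embedding types land in one representation space. Structure vectors are
#' additionally trained on skip-gram pairs from biased random walks. Text
#' vectors are produced per edge by the convolution + mutual-attention
#' encoder (see [mutual_attention()]); gradients flow into the word table,
#' the convolution filters and the attentive matrix.
#'
#' The per-epoch objective recorded in `loss_history` is the mean per-edge
#' objective evaluated with a fixed set of negatives drawn once before
#' training, so epochs are comparable; the pre-training value is kept in
#' `initial_objective`.
#'
#' @param graph An `ontology_graph` with resolved texts (see
#'   [resolve_texts()]).
#' @param config A [joint_config()].
#' @return An `ontropy_model`: vertex ids, structure matrix `S`, word table
#'   `Wword` (rownames = vocabulary), convolution filters `Wconv`, bias
#'   `bconv`, attentive matrix `A`, per-vertex token ids, the training
#'   config, `loss_history` (one value per epoch) and `initial_objective`.
#' @export
train_embeddings <- function(graph, config = joint_config()) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (any(is.na(graph$vertices$text))) {
    abort("train_embeddings: texts are unresolved; call resolve_texts() first",
          class = "ontropy_config_error")
  }
  if (nrow(graph$edges) == 0L) {
    abort("train_embeddings: graph has no edges", class = "ontropy_config_error")
  }
  withr::with_seed(config$seed, train_embeddings_impl(graph, config))
}

train_embeddings_impl <- function(graph, config) {
  ids <- graph$vertices$id
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  d <- config$dim

  vocab <- build_vocab(graph$vertices$text)
  token_ids <- lapply(graph$vertices$text, tokens_to_ids,
                      vocab = vocab, max_len = config$max_text_len)

  par <- new.env(parent = emptyenv())
  par$S <- matrix(runif(n * d, -0.5, 0.5) / d, n, d, dimnames = list(ids, NULL))
  par$Wword <- matrix(runif(length(vocab) * d, -0.5, 0.5) / d, length(vocab), d,
                      dimnames = list(vocab, NULL))
  par$Wconv <- matrix(runif(d * config$conv_window * d, -0.5, 0.5) /
                        sqrt(config$conv_window * d),
                      d, config$conv_window * d)
  par$bconv <- rep(0, d)
  par$A <- diag(d) + matrix(runif(d * d, -0.05, 0.05), d, d)

  ef <- unname(idx[graph$edges$from])
  et <- unname(idx[graph$edges$to])
  n_edges <- length(ef)

  walk_pairs <- NULL
  if (isTRUE(config$use_walks)) {
    corpus <- generate_walks(graph, walk_length = config$walk_length,
                             walks_per_vertex = config$walks_per_vertex,
                             return_param = config$return_param,
                             inout_param = config$inout_param, seed = NULL)
    wp <- skipgram_pairs(corpus, window = config$walk_window)
    if (nrow(wp) > 0L) {
      walk_pairs <- cbind(unname(idx[wp[, 1]]), unname(idx[wp[, 2]]))
    }
  }
  pairs_per_epoch <- config$walk_pairs_per_epoch %||% (5L * n_edges)

  # fixed evaluation negatives (per edge), for comparable epoch objectives
  eval_negs <- lapply(seq_len(n_edges), function(e) sample_negatives(n, ef[e], et[e], config$negatives))

  model <- list(ids = ids, idx = idx, dim = d, par = par, vocab = vocab,
                token_ids = token_ids, config = config, graph = graph)
  class(model) <- "ontropy_model"

  objective <- function() {
    mean(vapply(seq_len(n_edges), function(e) {
      edge_objective_idx(model, ef[e], et[e], eval_negs[[e]])
    }, numeric(1)))
  }
  initial <- objective()
  if (!is.finite(initial)) {
    abort("training objective non-finite at initialization",
          class = "ontropy_divergence_error")
  }

  total_steps <- max(1L, config$epochs * (n_edges +
    if (is.null(walk_pairs)) 0L else min(pairs_per_epoch, nrow(walk_pairs))))
  step <- 0L
  lr0 <- config$learning_rate
  lr_at <- function(s) lr0 * (1 - 0.9 * (s - 1) / total_steps)

  loss_history <- numeric(config$epochs)
  acc <- new.env(parent = emptyenv())
  for (epoch in seq_len(config$epochs)) {
    for (e in sample.int(n_edges)) {
      step <- step + 1L
      if (runif(1) < 0.5) { u <- ef[e]; v <- et[e] } else { u <- et[e]; v <- ef[e] }
      negs <- sample_negatives(n, u, v, config$negatives)
      edge_sgd_step(model, u, v, negs, lr_at(step), acc)
    }
    if (!is.null(walk_pairs)) {
      take <- sample.int(nrow(walk_pairs), min(pairs_per_epoch, nrow(walk_pairs)))
      for (r in take) {
        step <- step + 1L
        u <- walk_pairs[r, 1]; v <- walk_pairs[r, 2]
        negs <- sample_negatives(n, u, v, config$negatives)
        structure_sgd_step(par, u, v, negs, lr_at(step))
      }
    }
    loss_history[epoch] <- objective()
    if (!is.finite(loss_history[epoch])) {
      abort(paste0("training diverged (non-finite objective) at epoch ", epoch),
            class = "ontropy_divergence_error")
    }
  }

  model$loss_history <- loss_history
  model$initial_objective <- initial
  model
}

sample_negatives <- function(n, u, v, k) {
  pool <- setdiff(seq_len(n), c(u, v))
  if (length(pool) == 0L) return(integer(0))
  pool[sample.int(length(pool), min(k, length(pool)))]
}

# one negative-sampling SGD ascent step on the structure term only
structure_sgd_step <- function(par, u, v, negs, lr) {
  us <- par$S[u, ]; vs <- par$S[v, ]
  c1 <- 1 - sigmoid(sum(us * vs))
  gu <- c1 * vs
  gv <- c1 * us
  if (length(negs) > 0L) {
    Ks <- par$S[negs, , drop = FALSE]
    cn <- 1 - sigmoid(-as.vector(Ks %*% us))
    gu <- gu - colSums(cn * Ks)
    par$S[negs, ] <- par$S[negs, , drop = FALSE] - lr * outer(cn, us)
  }
  par$S[u, ] <- us + lr * gu
  par$S[v, ] <- vs + lr * gv
  invisible(NULL)
}

# full four-term ascent step for one (oriented) edge
edge_sgd_step <- function(model, u, v, negs, lr, acc) {
  par <- model$par
  cfg <- model$config
  d <- model$dim
  al <- cfg$alpha; be <- cfg$beta; ga <- cfg$gamma

  us <- par$S[u, ]; vs <- par$S[v, ]
  pair_uv <- text_pair_forward(model$token_ids[[u]], model$token_ids[[v]],
                               par$Wword, par$Wconv, par$bconv, par$A,
                               cfg$conv_window)
  u_t <- pair_uv$u_t; v_t <- pair_uv$v_t

  nneg <- length(negs)
  pairs_uk <- vector("list", nneg)
  K_t <- matrix(0, nneg, d)
  for (k in seq_len(nneg)) {
    pairs_uk[[k]] <- text_pair_forward(model$token_ids[[u]],
                                       model$token_ids[[negs[k]]],
                                       par$Wword, par$Wconv, par$bconv, par$A,
                                       cfg$conv_window)
    K_t[k, ] <- pairs_uk[[k]]$v_t
  }
  K_s <- par$S[negs, , drop = FALSE]

  # L_s: log p(v_s | u_s)
  c1 <- 1 - sigmoid(sum(us * vs))
  gUs <- c1 * vs; gVs <- c1 * us
  gKs <- matrix(0, nneg, d)
  if (nneg > 0L) {
    cn1 <- 1 - sigmoid(-as.vector(K_s %*% us))
    gUs <- gUs - colSums(cn1 * K_s)
    gKs <- gKs - outer(cn1, us)
  }
  # L_tt: log p(v_t | u_t)
  c2 <- 1 - sigmoid(sum(u_t * v_t))
  gUt <- al * c2 * v_t; gVt <- al * c2 * u_t
  gKt <- matrix(0, nneg, d)
  if (nneg > 0L) {
    cn2 <- 1 - sigmoid(-as.vector(K_t %*% u_t))
    gUt <- gUt - al * colSums(cn2 * K_t)
    gKt <- gKt - al * outer(cn2, u_t)
  }
  # L_ts: log p(v_t | u_s)
  c3 <- 1 - sigmoid(sum(us * v_t))
  gUs <- gUs + be * c3 * v_t
  gVt <- gVt + be * c3 * us
  if (nneg > 0L) {
    cn3 <- 1 - sigmoid(-as.vector(K_t %*% us))
    gUs <- gUs - be * colSums(cn3 * K_t)
    gKt <- gKt - be * outer(cn3, us)
  }
  # L_st: log p(v_s | u_t)
  c4 <- 1 - sigmoid(sum(u_t * vs))
  gUt <- gUt + ga * c4 * vs
  gVs <- gVs + ga * c4 * u_t
  if (nneg > 0L) {
    cn4 <- 1 - sigmoid(-as.vector(K_s %*% u_t))
    gUt <- gUt - ga * colSums(cn4 * K_s)
    gKs <- gKs - ga * outer(cn4, u_t)
  }

  par$S[u, ] <- us + lr * gUs
  par$S[v, ] <- vs + lr * gVs
  if (nneg > 0L) par$S[negs, ] <- K_s + lr * gKs

  acc$gW <- matrix(0, nrow(par$Wword), d)
  acc$gWc <- matrix(0, d, ncol(par$Wconv))
  acc$gb <- rep(0, d)
  acc$gA <- matrix(0, d, d)
  text_pair_backward(pair_uv, gUt, gVt, par$Wconv, par$A, cfg$conv_window, acc)
  zero <- rep(0, d)
  for (k in seq_len(nneg)) {
    text_pair_backward(pairs_uk[[k]], zero, gKt[k, ], par$Wconv, par$A,
                       cfg$conv_window, acc)
  }
  par$Wword <- par$Wword + lr * acc$gW
  par$Wconv <- par$Wconv + lr * acc$gWc
  par$bconv <- par$bconv + lr * acc$gb
  par$A <- par$A + lr * acc$gA
  invisible(NULL)
}

# per-edge objective at integer indices with given negatives (sampled form)
edge_objective_idx <- function(model, u, v, negs) {
  par <- model$par
  cfg <- model$config
  us <- par$S[u, ]; vs <- par$S[v, ]
  pair_uv <- text_pair_forward(model$token_ids[[u]], model$token_ids[[v]],
                               par$Wword, par$Wconv, par$bconv, par$A,
                               cfg$conv_window)
  u_t <- pair_uv$u_t; v_t <- pair_uv$v_t
  nneg <- length(negs)
  K_t <- matrix(0, nneg, model$dim)
  for (k in seq_len(nneg)) {
    K_t[k, ] <- text_pair_forward(model$token_ids[[u]],
                                  model$token_ids[[negs[k]]],
                                  par$Wword, par$Wconv, par$bconv, par$A,
                                  cfg$conv_window)$v_t
  }
  K_s <- par$S[negs, , drop = FALSE]
  term <- function(x, y, Kmat) {
    log_sigmoid(sum(x * y)) +
      if (nneg > 0L) sum(log_sigmoid(-as.vector(Kmat %*% x))) else 0
  }
  term(us, vs, K_s) +
    cfg$alpha * term(u_t, v_t, K_t) +
    cfg$beta * term(us, v_t, K_t) +
    cfg$gamma * term(u_t, vs, K_s)
}

#' @export
print.ontropy_model <- function(x, ...) {
  cat("<ontropy_model> ", length(x$ids), " vertices, dim ", x$dim,
      ", vocab ", length(x$vocab), ", ", length(x$loss_history %||% numeric(0)),
      " epoch(s)\n", sep = "")
  if (!is.null(x$loss_history) && length(x$loss_history) > 0L) {
    cat("  objective: ", format(x$initial_objective, digits = 6), " -> ",
        format(tail(x$loss_history, 1), digits = 6), "\n", sep = "")
  }
  invisible(x)
}
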