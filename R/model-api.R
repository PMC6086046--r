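#' Structure-based log conditional probability of an edge
#'
#' `log p(v_s | u_s)` under the softmax over all vertex structure vectors:
#' exactly, when `negatives` is `NULL` and the graph is small enough, or as
#' the standard negative-sampling estimate
#' `log sigma(u.v) + sum_k log sigma(-u.k)` otherwise.
#'
#' @param model An `ontropy_model`.
#' @param edge Character vector of two vertex ids `(u, v)`.
#' @param negatives Optional character vector of negative-sample vertex ids;
#'   `NULL` requests the exact softmax.
#' @return A scalar log probability (exact mode) or sampled objective value.
#' @export
structure_loss <- function(model, edge, negatives = NULL) {
  stopifnot(inherits(model, "ontropy_model"), length(edge) == 2L)
  ui <- vertex_index(model, edge[1]); vi <- vertex_index(model, edge[2])
  S <- model$par$S
  us <- S[ui, ]
  if (is.null(negatives)) {
    check_exact_allowed(model)
    sum(us * S[vi, ]) - logsumexp(as.vector(S %*% us))
  } else {
    if (length(negatives) == 0L) {
      abort("structure_loss: empty negative sample with approximation requested",
            class = "ontropy_config_error")
    }
    ks <- vapply(negatives, function(id) vertex_index(model, id), integer(1))
    Ks <- S[ks, , drop = FALSE]
    log_sigmoid(sum(us * S[vi, ])) + sum(log_sigmoid(-as.vector(Ks %*% us)))
  }
}

#' Joint per-edge objective
#'
#' Evaluates `L_s + alpha L_tt + beta L_ts + gamma L_st` for one oriented
#' edge, each term a log conditional probability of softmax form. Text
#' vectors are context-dependent: the candidate text vector of any vertex
#' `k` is its attention-pooled vector conditioned on `u` (the column side
#' of the mutual attention between `u`'s and `k`'s convolved texts). With
#' `exact = TRUE` the softmax normalizes over every vertex (permitted only
#' up to `exact_softmax_cutoff` vertices); otherwise `negatives` supplies
#' the sampled denominator.
#'
#' @inheritParams structure_loss
#' @param exact Use the exact softmax denominator over all vertices.
#' @return A scalar objective value.
#' @export
edge_objective <- function(model, edge, negatives = NULL,
                           exact = is.null(negatives)) {
  stopifnot(inherits(model, "ontropy_model"), length(edge) == 2L)
  ui <- vertex_index(model, edge[1]); vi <- vertex_index(model, edge[2])
  cfg <- model$config
  if (exact) {
    check_exact_allowed(model)
    S <- model$par$S
    n <- length(model$ids)
    us <- S[ui, ]; vs <- S[vi, ]
    Kt <- t(vapply(seq_len(n), function(k) context_text_vector(model, ui, k),
                   numeric(model$dim)))
    u_t <- first_side_text_vector(model, ui, vi)
    v_t <- Kt[vi, ]
    (sum(us * vs) - logsumexp(as.vector(S %*% us))) +
      cfg$alpha * (sum(u_t * v_t) - logsumexp(as.vector(Kt %*% u_t))) +
      cfg$beta * (sum(us * v_t) - logsumexp(as.vector(Kt %*% us))) +
      cfg$gamma * (sum(u_t * vs) - logsumexp(as.vector(S %*% u_t)))
  } else {
    if (is.null(negatives) || length(negatives) == 0L) {
      abort("edge_objective: empty negative sample with approximation requested",
            class = "ontropy_config_error")
    }
    ks <- vapply(negatives, function(id) vertex_index(model, id), integer(1))
    edge_objective_idx(model, ui, vi, ks)
  }
}

vertex_index <- function(model, id) {
  i <- unname(model$idx[as.character(id)])
  if (length(i) != 1L || is.na(i)) {
    abort(paste0("unknown vertex id: ", id), class = "ontropy_lookup_error")
  }
  i
}

check_exact_allowed <- function(model) {
  n <- length(model$ids)
  cutoff <- model$config$exact_softmax_cutoff
  if (n > cutoff) {
    abort(paste0("exact softmax requested for n = ", n,
                 " vertices (cutoff ", cutoff, "); pass negatives instead"),
          class = "ontropy_config_error")
  }
}

# text vector of vertex k conditioned on u (column side of the pair (u, k))
context_text_vector <- function(model, ui, k) {
  par <- model$par
  text_pair_forward(model$token_ids[[ui]], model$token_ids[[k]],
                    par$Wword, par$Wconv, par$bconv, par$A,
                    model$config$conv_window)$v_t
}

# text vector of u conditioned on v (row side of the pair (u, v))
first_side_text_vector <- function(model, ui, vi) {
  par <- model$par
  text_pair_forward(model$token_ids[[ui]], model$token_ids[[vi]],
                    par$Wword, par$Wconv, par$bconv, par$A,
                    model$config$conv_window)$u_t
}

#' Extract vertex embeddings from a trained model
#'
#' The full embedding of a vertex is the concatenation of its structure
#' vector and its aggregate text vector; the aggregate text vector is the
#' mean of the vertex's context text vectors over its graph neighbours
#' (attention yields one text vector per neighbour; averaging gives the
#' single order-independent vector per vertex that the information-gain
#' matrix needs for arbitrary vertex pairs). An isolated vertex uses its
#' self-conditioned text vector.
#'
#' @param model An `ontropy_model`.
#' @param type `"full"` (structure + text, width `2 * dim`),
#'   `"structure"`, or `"text"`.
#' @return A numeric matrix, one row per vertex, rownames = vertex ids.
#' @export
vertex_embeddings <- function(model, type = c("full", "structure", "text")) {
  type <- match.arg(type)
  S <- model$par$S
  if (type == "structure") return(S)
  n <- length(model$ids)
  idx <- model$idx
  nb <- vector("list", n)
  e <- model$graph$edges
  if (nrow(e) > 0L) {
    ef <- unname(idx[e$from]); et <- unname(idx[e$to])
    for (k in seq_along(ef)) {
      nb[[ef[k]]] <- c(nb[[ef[k]]], et[k])
      nb[[et[k]]] <- c(nb[[et[k]]], ef[k])
    }
    nb <- lapply(nb, unique)
  }
  Tm <- matrix(0, n, model$dim, dimnames = list(model$ids, NULL))
  for (v in seq_len(n)) {
    ws <- nb[[v]]
    if (is.null(ws) || length(ws) == 0L) ws <- v
    vecs <- vapply(ws, function(w) context_text_vector(model, w, v),
                   numeric(model$dim))
    Tm[v, ] <- rowMeans(matrix(vecs, nrow = model$dim))
  }
  if (type == "text") return(Tm)
  out <- cbind(S, Tm)
  rownames(out) <- model$ids
  out
}

#' @rdname vertex_embeddings
#' @param vertex A single vertex id.
#' @export
final_vertex_embedding <- function(model, vertex) {
  vertex_index(model, vertex)  # errors early on unknown ids
  vertex_embeddings(model, "full")[as.character(vertex), ]
}

#' Save or load a trained model checkpoint
#'
#' Writes a directory of plain-text files: structure vectors and word table
#' in the word-vector text format, convolution filters/bias and attentive
#' matrix as dense TSV, the graph as edge list + vertex table, and a JSON
#' manifest of hyperparameters and training history.
#'
#' @param model An `ontropy_model`.
#' @param dir Checkpoint directory (created if absent).
#' @return `load_model()` returns the reconstructed `ontropy_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_embeddings(model$par$S, file.path(dir, "structure_vectors.txt"))
  write_embeddings(model$par$Wword, file.path(dir, "word_vectors.txt"))
  Wc <- model$par$Wconv
  dimnames(Wc) <- list(paste0("f", seq_len(nrow(Wc))), paste0("x", seq_len(ncol(Wc))))
  write_matrix_tsv(Wc, file.path(dir, "conv_filters.tsv"))
  A <- model$par$A
  dimnames(A) <- list(paste0("r", seq_len(nrow(A))), paste0("c", seq_len(ncol(A))))
  write_matrix_tsv(A, file.path(dir, "attentive_matrix.tsv"))
  writeLines(format(model$par$bconv, digits = 17), file.path(dir, "conv_bias.txt"))
  write_ontology_graph(model$graph, file.path(dir, "edges.tsv"),
                       file.path(dir, "vertices.tsv"))
  manifest <- list(
    config = unclass(model$config),
    loss_history = model$loss_history,
    initial_objective = model$initial_objective
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(model)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(joint_config, manifest$config[names(manifest$config) %in%
                                                 names(formals(joint_config))])
  graph <- read_ontology_graph(file.path(dir, "edges.tsv"),
                               file.path(dir, "vertices.tsv"))
  S <- read_embeddings(file.path(dir, "structure_vectors.txt"))
  Wword <- read_embeddings(file.path(dir, "word_vectors.txt"))
  read_mat <- function(path) {
    df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
    as.matrix(df[, -1, drop = FALSE])
  }
  par <- new.env(parent = emptyenv())
  par$S <- S
  par$Wword <- Wword
  par$Wconv <- unname(read_mat(file.path(dir, "conv_filters.tsv")))
  par$A <- unname(read_mat(file.path(dir, "attentive_matrix.tsv")))
  par$bconv <- as.numeric(readLines(file.path(dir, "conv_bias.txt")))
  vocab <- rownames(Wword)
  model <- list(
    ids = rownames(S), idx = setNames(seq_len(nrow(S)), rownames(S)),
    dim = ncol(S), par = par, vocab = vocab,
    token_ids = lapply(graph$vertices$text, tokens_to_ids,
                       vocab = vocab, max_len = cfg$max_text_len),
    config = cfg, graph = graph,
    loss_history = manifest$loss_history,
    initial_objective = manifest$initial_objective
  )
  class(model) <- "ontropy_model"
  model
}
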