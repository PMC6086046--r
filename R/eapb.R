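#' Relevancy of two vertex embeddings
#'
#' Cosine similarity mapped onto `[0, 1]`. The default `"affine"` map is
#' `(1 + cos) / 2`, keeping the weighted concept distribution non-negative
#' while preserving the ordering of similarities; `"clamp"` instead
#' truncates negative cosines at zero. A zero vector has undefined cosine;
#' its relevancy is defined as 0 with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @param map `"affine"` (default) or `"clamp"`.
#' @return A similarity in `[0, 1]`.
#' @export
pair_relevancy <- function(x, y, map = c("affine", "clamp")) {
  map <- match.arg(map)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warn("pair_relevancy: zero vector; similarity defined as 0")
    return(0)
  }
  cs <- sum(x * y) / (nx * ny)
  cs <- max(-1, min(1, cs))
  if (map == "affine") (1 + cs) / 2 else max(0, cs)
}

#' Information-gain matrix from embeddings and shortest paths
#'
#' For each reachable pair `(u, v)`, the information gain is the embedding
#' relevancy divided by the shortest-path hop count, `O_uv = rel(u, v) /
#' D_uv`, so that the weight of a long path is not counted multiple times.
#' Unreachable pairs and the diagonal are 0.
#'
#' @param emb Numeric matrix of vertex embeddings (rows = vertices, rownames
#'   = ids).
#' @param D Shortest-path matrix from [shortest_path_matrix()], rows/cols
#'   in the same vertex order.
#' @param map Cosine map passed to [pair_relevancy()].
#' @return A symmetric non-negative matrix `O` with zero diagonal and
#'   vertex-id dimnames.
#' @export
information_gain <- function(emb, D, map = c("affine", "clamp")) {
  map <- match.arg(map)
  stopifnot(is.matrix(emb), nrow(emb) == nrow(D), nrow(D) == ncol(D))
  if (!is.null(rownames(emb)) && !is.null(rownames(D))) {
    stopifnot(identical(rownames(emb), rownames(D)))
  }
  n <- nrow(emb)
  norms <- sqrt(rowSums(emb^2))
  zero <- norms == 0
  if (any(zero)) {
    warn(paste0("information_gain: ", sum(zero),
                " zero embedding(s); their relevancies set to 0"))
    norms[zero] <- 1
  }
  cs <- tcrossprod(emb / norms)
  cs[zero, ] <- 0; cs[, zero] <- 0
  cs <- pmin(pmax(cs, -1), 1)
  rel <- if (map == "affine") (1 + cs) / 2 else pmax(cs, 0)
  if (any(zero)) { rel[zero, ] <- 0; rel[, zero] <- 0 }
  O <- rel / D
  O[!is.finite(O)] <- 0   # unreachable pairs and the diagonal
  diag(O) <- 0
  dimnames(O) <- dimnames(D)
  O
}

#' Weighted concept distribution
#'
#' The path-and-text-aware concept distribution: each concept's probability
#' is its share of connectivity mass after weighting by information gain,
#' `P'_k = sum_{u != k} C_uk O_uk / sum_{u,v} C_uv O_uv`. With `O` all ones
#' off-diagonal this reduces exactly to the unweighted
#' [concept_distribution()].
#'
#' @param C A connectivity matrix.
#' @param O An information-gain matrix of the same shape.
#' @return A named probability vector summing to 1.
#' @export
weighted_distribution <- function(C, O) {
  stopifnot(is.matrix(C), is.matrix(O), all(dim(C) == dim(O)))
  W <- C * O
  total <- sum(W)
  if (total <= 0) {
    abort("degenerate weighted distribution: no connected pair has positive gain",
          class = "ontropy_degenerate_error")
  }
  colSums(W) / total
}

#' Entropy-aware path-based (EAPB) entropy of an ontology
#'
#' Runs the full metric pipeline: vertex embeddings from the trained model,
#' shortest-path hop counts, the information-gain matrix, the weighted
#' concept distribution, and its Shannon entropy in bits. Lower entropy
#' indicates a more organised (less redundant) ontology once compared
#' across ontologies of similar size; the per-vertex contributions
#' `-P'_k log2 P'_k` localise where connectivity mass concentrates.
#'
#' @param graph An `ontology_graph` (the one the model was trained on).
#' @param model An `ontropy_model` covering all vertices. May be `NULL`
#'   when `uniform_gain = TRUE`, since the baseline reduction uses no
#'   embeddings.
#' @param connectivity `"reachability"` (default) or `"adjacency"` (see
#'   [connectivity_matrix()]).
#' @param similarity `"full-embedding"` (structure + text, the default) or
#'   `"structure-only"` (the text-ablated variant).
#' @param uniform_gain If `TRUE`, overrides `O` with 1 for every connected
#'   pair, reproducing the unweighted baseline entropy exactly.
#' @param map Cosine map passed to [pair_relevancy()].
#' @return An `entropy_report`: a list with `s_prime` (bits), `p_prime`
#'   (named probability vector), `contributions` (tibble of per-vertex
#'   `id`, `p_prime`, `contribution_bits`), `baseline_entropy`, and the
#'   mode flags.
#' @export
eapb_entropy <- function(graph, model = NULL,
                         connectivity = c("reachability", "adjacency"),
                         similarity = c("full-embedding", "structure-only"),
                         uniform_gain = FALSE, map = c("affine", "clamp")) {
  connectivity <- match.arg(connectivity)
  similarity <- match.arg(similarity)
  map <- match.arg(map)
  stopifnot(inherits(graph, "ontology_graph"))
  if (!uniform_gain) {
    if (!inherits(model, "ontropy_model")) {
      abort("a trained model is required unless uniform_gain = TRUE",
            class = "ontropy_config_error")
    }
    if (!all(graph$vertices$id %in% model$ids)) {
      abort("model does not cover all graph vertices",
            class = "ontropy_lookup_error")
    }
  }
  C <- connectivity_matrix(graph, mode = connectivity)
  ids <- rownames(C)
  D <- shortest_path_matrix(graph)[ids, ids]
  if (uniform_gain) {
    O <- matrix(1, nrow(C), ncol(C), dimnames = dimnames(C))
    diag(O) <- 0
    O[!is.finite(D) & row(D) != col(D)] <- 0
  } else {
    emb_type <- if (similarity == "structure-only") "structure" else "full"
    emb <- vertex_embeddings(model, emb_type)[ids, , drop = FALSE]
    O <- information_gain(emb, D, map = map)
  }
  p <- weighted_distribution(C, O)
  s <- shannon_entropy(p)
  contrib <- ifelse(p > 0, -p * log2(p), 0)
  baseline <- shannon_entropy(concept_distribution(C))
  structure(
    list(
      s_prime = s,
      p_prime = p,
      contributions = tibble(id = ids, p_prime = unname(p),
                             contribution_bits = unname(contrib)),
      baseline_entropy = baseline,
      n_vertices = length(ids),
      connectivity_mode = connectivity,
      similarity_mode = if (uniform_gain) "uniform" else similarity,
      uniform_gain = uniform_gain,
      cosine_map = map
    ),
    class = "entropy_report"
  )
}

#' Text-ablated EAPB entropy
#'
#' The identical pipeline with relevancies computed on structure vectors
#' only, isolating what the textual channel contributes to the metric.
#'
#' @inheritParams eapb_entropy
#' @return An `entropy_report` with `similarity_mode = "structure-only"`.
#' @export
ablate_text <- function(graph, model,
                        connectivity = c("reachability", "adjacency"),
                        map = c("affine", "clamp")) {
  eapb_entropy(graph, model, connectivity = connectivity,
               similarity = "structure-only", map = map)
}

#' @export
print.entropy_report <- function(x, ...) {
  cat("<entropy_report> S' = ", format(x$s_prime, digits = 6), " bits over ",
      x$n_vertices, " concepts\n", sep = "")
  cat("  connectivity: ", x$connectivity_mode,
      "; similarity: ", x$similarity_mode,
      "; baseline entropy: ", format(x$baseline_entropy, digits = 6),
      " bits\n", sep = "")
  invisible(x)
}
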