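#' Connectivity matrix of a class graph
#'
#' A 0/1 matrix recording which vertex pairs count as connected. In
#' `"adjacency"` mode an entry is 1 iff the pair is an edge; in
#' `"reachability"` mode it is 1 iff the two vertices lie in the same
#' connected component. The diagonal is zero and the matrix symmetric in
#' both modes. Reachability is the package default for the entropy metric:
#' the point of a path-based measure is that non-adjacent but connected
#' concepts still exchange information.
#'
#' @param graph An `ontology_graph`.
#' @param mode `"reachability"` (default) or `"adjacency"`.
#' @return A symmetric 0/1 numeric matrix with vertex ids as dimnames.
#' @export
connectivity_matrix <- function(graph, mode = c("reachability", "adjacency")) {
  mode <- match.arg(mode)
  g <- as_igraph(graph)
  ids <- igraph::V(g)$name
  n <- length(ids)
  if (mode == "adjacency") {
    C <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    C[C > 1] <- 1
  } else {
    comp <- igraph::components(g)$membership
    C <- outer(comp, comp, "==") * 1
  }
  diag(C) <- 0
  dimnames(C) <- list(ids, ids)
  attr(C, "mode") <- mode
  C
}

#' Shortest-path hop-count matrix
#'
#' All-pairs unweighted shortest-path lengths (breadth-first hop counts).
#' Pairs in different components are `Inf`; the diagonal is zero.
#'
#' @param graph An `ontology_graph`.
#' @return A symmetric numeric matrix with vertex ids as dimnames.
#' @export
shortest_path_matrix <- function(graph) {
  g <- as_igraph(graph)
  D <- igraph::distances(g, algorithm = "unweighted")
  dimnames(D) <- list(igraph::V(g)$name, igraph::V(g)$name)
  D
}

#' Concept probability distribution from a connectivity matrix
#'
#' The baseline (unweighted) concept distribution: each concept's
#' probability is its share of total connectivity mass,
#' `P_k = sum_u C_uk / sum_{u,v} C_uv`, summed over ordered pairs.
#' In adjacency mode this reduces to `degree(k) / (2 |E|)`.
#'
#' @param C A connectivity matrix (see [connectivity_matrix()]), or more
#'   generally any symmetric non-negative weight matrix with zero diagonal.
#' @return A named probability vector summing to 1.
#' @export
concept_distribution <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  total <- sum(C)
  if (total <= 0) {
    abort("degenerate concept distribution: connectivity matrix has no mass (edgeless graph?)",
          class = "ontropy_degenerate_error")
  }
  colSums(C) / total
}

#' Shannon entropy of a probability vector, in bits
#'
#' `S = -sum p log2 p` with the `0 log 0 = 0` convention. Bounded by
#' `log2(n)`, attained only by the uniform distribution.
#'
#' @param p A non-negative numeric vector summing to 1.
#' @return Entropy in bits (a scalar).
#' @export
shannon_entropy <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0))
  p <- p[p > 0]
  -sum(p * log2(p))
}
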