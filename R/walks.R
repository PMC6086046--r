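#' Generate biased second-order random walks
#'
#' Samples node2vec-style walks over the class graph: from the current
#' vertex, the next step is drawn among its neighbours with weight `1/p`
#' for stepping back to the previous vertex (`return_param`), 1 for moving
#' to a neighbour of the previous vertex, and `1/q` for moving outward
#' (`inout_param`). The walk corpus drives the structure-based skip-gram
#' objective. Isolated vertices yield single-vertex walks.
#'
#' @param graph An `ontology_graph`.
#' @param walk_length Maximum walk length (vertices per walk).
#' @param walks_per_vertex Number of walks started at each vertex.
#' @param return_param,inout_param The node2vec bias parameters p and q.
#' @param seed Integer seed; `NULL` uses the current RNG state (for callers
#'   that already manage seeding).
#' @return A `walk_corpus`: a list with `walks` (list of vertex-id vectors)
#'   and the sampling parameters.
#' @export
generate_walks <- function(graph, walk_length = 40L, walks_per_vertex = 10L,
                           return_param = 1, inout_param = 1, seed = 1L) {
  stopifnot(inherits(graph, "ontology_graph"), walk_length >= 1L)
  body <- function() {
    ids <- graph$vertices$id
    n <- length(ids)
    idx <- setNames(seq_len(n), ids)
    nbrs <- vector("list", n)
    for (i in seq_len(n)) nbrs[[i]] <- integer(0)
    if (nrow(graph$edges) > 0L) {
      ef <- idx[graph$edges$from]
      et <- idx[graph$edges$to]
      for (k in seq_along(ef)) {
        nbrs[[ef[k]]] <- c(nbrs[[ef[k]]], et[k])
        nbrs[[et[k]]] <- c(nbrs[[et[k]]], ef[k])
      }
      nbrs <- lapply(nbrs, function(x) sort(unique(x)))
    }
    n_isolated <- 0L
    walks <- vector("list", n * walks_per_vertex)
    w <- 0L
    for (rep_i in seq_len(walks_per_vertex)) {
      for (start in seq_len(n)) {
        walk <- integer(walk_length)
        walk[1] <- start
        len <- 1L
        if (length(nbrs[[start]]) == 0L) {
          n_isolated <- n_isolated + 1L
        } else {
          while (len < walk_length) {
            cur <- walk[len]
            cand <- nbrs[[cur]]
            if (len == 1L) {
              nxt <- cand[sample.int(length(cand), 1L)]
            } else {
              prev <- walk[len - 1L]
              wts <- ifelse(cand == prev, 1 / return_param,
                            ifelse(cand %in% nbrs[[prev]], 1, 1 / inout_param))
              nxt <- cand[sample.int(length(cand), 1L, prob = wts)]
            }
            len <- len + 1L
            walk[len] <- nxt
          }
        }
        w <- w + 1L
        walks[[w]] <- ids[walk[seq_len(len)]]
      }
    }
    if (n_isolated > 0L) {
      inform(paste0("generate_walks: ", n_isolated,
                    " walk(s) truncated at isolated vertices"))
    }
    structure(
      list(walks = walks, walk_length = walk_length,
           walks_per_vertex = walks_per_vertex,
           return_param = return_param, inout_param = inout_param),
      class = "walk_corpus"
    )
  }
  if (is.null(seed)) body() else withr::with_seed(seed, body())
}

#' Skip-gram training pairs from a walk corpus
#'
#' Expands each walk into (center, context) vertex pairs within a symmetric
#' window, the standard skip-gram context extraction.
#'
#' @param corpus A `walk_corpus`.
#' @param window Context window half-width.
#' @return A two-column character matrix (`center`, `context`).
#' @export
skipgram_pairs <- function(corpus, window = 5L) {
  stopifnot(inherits(corpus, "walk_corpus"))
  out <- vector("list", length(corpus$walks))
  for (k in seq_along(corpus$walks)) {
    walk <- corpus$walks[[k]]
    L <- length(walk)
    if (L < 2L) next
    centers <- character(0); contexts <- character(0)
    for (i in seq_len(L)) {
      lo <- max(1L, i - window); hi <- min(L, i + window)
      ctx <- setdiff(seq(lo, hi), i)
      centers <- c(centers, rep(walk[i], length(ctx)))
      contexts <- c(contexts, walk[ctx])
    }
    out[[k]] <- cbind(centers, contexts)
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(character(0), 0, 2)
  colnames(m) <- c("center", "context")
  m
}
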