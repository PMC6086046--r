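# Fixtures are built in code at test time; nothing binary is stored.

# Construct an ontology_graph directly from an edge list. Ids double as
# labels; every vertex gets a one-token definition unless texts are given.
make_graph <- function(edges, ids = NULL, texts = NULL, relations = NULL) {
  edges <- matrix(as.character(edges), ncol = 2)
  ids <- ids %||% sort(unique(as.vector(edges)))
  if (is.null(texts)) texts <- paste("concept", tolower(ids))
  v <- tibble::tibble(
    id = ids, label = ids, definition = texts,
    text = NA_character_, text_source = NA_character_
  )
  e <- tibble::tibble(
    from = edges[, 1], to = edges[, 2],
    relation = relations %||% rep("subClassOf", nrow(edges))
  )
  g <- structure(list(vertices = v, edges = e), class = "ontology_graph")
  ontropy::resolve_texts(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

path_graph <- function(n) {
  ids <- LETTERS[seq_len(n)]
  make_graph(cbind(ids[-n], ids[-1]), ids = ids)
}

complete_graph <- function(n) {
  ids <- LETTERS[seq_len(n)]
  pairs <- t(utils::combn(ids, 2))
  make_graph(pairs, ids = ids)
}

star_graph <- function(leaves = 3) {
  ids <- c("HUB", paste0("L", seq_len(leaves)))
  make_graph(cbind(ids[-1], "HUB"), ids = ids)
}

# Erdos-Renyi-ish random simple graph as an ontology_graph (connected or not).
random_graph <- function(n, p = 0.2, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("V%02d", seq_len(n))
    pairs <- t(utils::combn(seq_len(n), 2))
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
    make_graph(cbind(ids[pairs[keep, 1]], ids[pairs[keep, 2]]), ids = ids)
  })
}

# Independent all-pairs shortest-path oracle (Floyd-Warshall).
floyd_warshall <- function(graph) {
  ids <- graph$vertices$id
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  for (k in seq_len(nrow(graph$edges))) {
    u <- graph$edges$from[k]; v <- graph$edges$to[k]
    D[u, v] <- D[v, u] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Untrained (or briefly trained) model on a graph, for oracle tests.
tiny_model <- function(graph, dim = 4L, epochs = 0L, seed = 1L, ...) {
  ontropy::train_embeddings(
    graph,
    ontropy::joint_config(dim = dim, epochs = epochs, seed = seed,
                          negatives = 2L, use_walks = FALSE,
                          walks_per_vertex = 2L, walk_length = 10L, ...)
  )
}

write_fixture <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Three-class toy ontology in each supported dialect (identical content).
toy_rdfxml <- function() write_fixture(c(
  '<?xml version="1.0"?>',
  '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
  '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
  '         xmlns:owl="http://www.w3.org/2002/07/owl#"',
  '         xmlns:obo="http://purl.obolibrary.org/obo/">',
  '  <owl:Class rdf:about="http://ex.org/o#A">',
  '    <rdfs:label>alpha process</rdfs:label>',
  '    <obo:IAO_0000115>a viral process</obo:IAO_0000115>',
  '  </owl:Class>',
  '  <owl:Class rdf:about="http://ex.org/o#B">',
  '    <rdfs:label>beta process</rdfs:label>',
  '    <rdfs:subClassOf rdf:resource="http://ex.org/o#A"/>',
  '  </owl:Class>',
  '  <owl:Class rdf:about="http://ex.org/o#C">',
  '    <rdfs:label>gamma process</rdfs:label>',
  '    <rdfs:subClassOf rdf:resource="http://ex.org/o#B"/>',
  '  </owl:Class>',
  '</rdf:RDF>'
), ".owl")

toy_turtle <- function() write_fixture(c(
  '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .',
  '@prefix owl: <http://www.w3.org/2002/07/owl#> .',
  '@prefix obo: <http://purl.obolibrary.org/obo/> .',
  '@prefix : <http://ex.org/o#> .',
  ':A a owl:Class ; rdfs:label "alpha process" ;',
  '   obo:IAO_0000115 "a viral process" .',
  ':B a owl:Class ; rdfs:label "beta process" ; rdfs:subClassOf :A .',
  ':C a owl:Class ; rdfs:label "gamma process" ; rdfs:subClassOf :B .'
), ".ttl")

toy_obo <- function() write_fixture(c(
  'format-version: 1.4',
  '',
  '[Term]',
  'id: http://ex.org/o#A',
  'name: alpha process',
  'def: "a viral process" []',
  '',
  '[Term]',
  'id: http://ex.org/o#B',
  'name: beta process',
  'is_a: http://ex.org/o#A ! alpha process',
  '',
  '[Term]',
  'id: http://ex.org/o#C',
  'name: gamma process',
  'is_a: http://ex.org/o#B'
), ".obo")

triple_key <- function(raw) {
  tr <- raw$triples
  sort(paste(tr$subject, tr$predicate, tr$object, tr$object_type, sep = "\r"))
}

edge_key <- function(graph) {
  e <- graph$edges
  sort(paste(pmin(e$from, e$to), pmax(e$from, e$to), e$relation))
}
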