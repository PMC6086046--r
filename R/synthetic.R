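#' Configuration for the synthetic-ontology generator
#'
#' Describes a seed-deterministic synthetic ontology: a `subClassOf`
#' backbone of a chosen topology, extra object-property cross edges, and
#' per-class definition texts drawn from topic-specific vocabularies
#' (topics = subtrees under the root, so the text channel carries real
#' signal about graph position). Redundancy is injected as duplicated
#' classes carrying near-copied texts; a fraction of classes can lack
#' definitions entirely to exercise the text-fallback cascade.
#'
#' @param n_classes Total classes including duplicates (>= 2).
#' @param topology `"tree"` (random recursive tree), `"scale-free"`
#'   (preferential attachment), or `"clustered"` (trees under cluster
#'   roots).
#' @param n_relations Number of random cross (object-property) edges.
#' @param vocab_size Number of distinct tokens in the generator vocabulary.
#' @param text_length_range Length-2 integer vector: min/max tokens per
#'   definition.
#' @param redundancy Fraction of classes that are duplicates of another
#'   class (in `[0, 1]`).
#' @param text_copy_noise Per-token replacement probability in duplicated
#'   texts.
#' @param missing_text_fraction Fraction of classes with no definition.
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_classes = 50L, topology = c("tree", "scale-free",
                                                       "clustered"),
                         n_relations = 8L, vocab_size = 120L,
                         text_length_range = c(6L, 20L), redundancy = 0,
                         text_copy_noise = 0.1, missing_text_fraction = 0,
                         seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_classes >= 2L, vocab_size >= 10L,
            length(text_length_range) == 2L,
            text_length_range[1] >= 1L,
            text_length_range[2] >= text_length_range[1])
  for (f in c(redundancy, text_copy_noise, missing_text_fraction)) {
    if (f < 0 || f > 1) {
      abort("synth_config: fractions must lie in [0, 1]",
            class = "ontropy_config_error")
    }
  }
  if (n_classes - round(redundancy * n_classes) < 2L) {
    abort("synth_config: redundancy leaves fewer than 2 original classes",
          class = "ontropy_config_error")
  }
  structure(as.list(environment())[names(formals(synth_config))],
            class = "synth_config")
}

#' Generate a synthetic ontology
#'
#' @param config A [synth_config()].
#' @return An `ontology_graph` with resolved texts. The attribute
#'   `ground_truth` is a list with `duplicates` (tibble of `dup`/`orig`
#'   vertex-id pairs) and `topics` (named topic index per backbone class).
#' @export
synth_ontology <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, synth_ontology_impl(config))
}

synth_ontology_impl <- function(cfg) {
  n_dup <- round(cfg$redundancy * cfg$n_classes)
  n_base <- cfg$n_classes - n_dup
  id_of <- function(i) sprintf("http://example.org/synthetic#C%04d", i)

  parent <- rep(NA_integer_, n_base)
  if (n_base >= 2L) {
    if (cfg$topology == "tree") {
      for (i in 2:n_base) parent[i] <- sample.int(i - 1L, 1L)
    } else if (cfg$topology == "scale-free") {
      deg <- rep(1, n_base)
      for (i in 2:n_base) {
        parent[i] <- sample.int(i - 1L, 1L, prob = deg[seq_len(i - 1L)])
        deg[parent[i]] <- deg[parent[i]] + 1
        deg[i] <- deg[i] + 1
      }
    } else { # clustered: trees hanging under cluster roots
      k <- max(2L, ceiling(n_base / 10))
      cluster <- integer(n_base)
      cluster[1] <- 0L
      roots <- seq(2L, min(k + 1L, n_base))
      parent[roots] <- 1L
      cluster[roots] <- seq_along(roots)
      if (n_base > max(roots)) {
        for (i in (max(roots) + 1L):n_base) {
          cl <- sample(seq_along(roots), 1L)
          members <- which(cluster == cl)
          parent[i] <- members[sample.int(length(members), 1L)]
          cluster[i] <- cl
        }
      }
    }
  }

  # topic = which child-of-root subtree a vertex falls in (root itself: 0)
  topic <- integer(n_base)
  root_children <- which(parent == 1L)
  for (i in seq_len(n_base)[-1]) {
    j <- i
    while (!is.na(parent[j]) && parent[j] != 1L) j <- parent[j]
    topic[i] <- match(j, root_children, nomatch = 0L)
  }
  n_topics <- max(1L, length(root_children))

  vocab <- sprintf("w%03d", seq_len(cfg$vocab_size))
  n_shared <- max(4L, round(0.3 * cfg$vocab_size))
  shared <- vocab[seq_len(n_shared)]
  rest <- vocab[-seq_len(n_shared)]
  topic_pool <- split(rest, rep_len(seq_len(n_topics), length(rest)))

  gen_text <- function(tp) {
    len <- sample(seq(cfg$text_length_range[1], cfg$text_length_range[2]), 1L)
    pool <- if (tp >= 1L && length(topic_pool[[tp]]) > 0L) topic_pool[[tp]] else shared
    from_topic <- runif(len) < 0.7
    toks <- ifelse(from_topic,
                   pool[sample.int(length(pool), len, replace = TRUE)],
                   shared[sample.int(length(shared), len, replace = TRUE)])
    paste(toks, collapse = " ")
  }
  defs <- vapply(seq_len(n_base), function(i) gen_text(topic[i]), character(1))

  edges_from <- integer(0); edges_to <- integer(0); edges_rel <- character(0)
  if (n_base >= 2L) {
    edges_from <- 2:n_base
    edges_to <- parent[2:n_base]
    edges_rel <- rep("subClassOf", n_base - 1L)
  }

  dup_of <- integer(0)
  if (n_dup > 0L) {
    dup_of <- sample.int(n_base, n_dup, replace = TRUE)
    for (k in seq_len(n_dup)) {
      i <- n_base + k
      orig <- dup_of[k]
      par_i <- if (is.na(parent[orig])) orig else parent[orig]
      edges_from <- c(edges_from, i)
      edges_to <- c(edges_to, par_i)
      edges_rel <- c(edges_rel, "subClassOf")
      toks <- strsplit(defs[orig], " ", fixed = TRUE)[[1]]
      repl <- runif(length(toks)) < cfg$text_copy_noise
      toks[repl] <- vocab[sample.int(length(vocab), sum(repl), replace = TRUE)]
      defs <- c(defs, paste(toks, collapse = " "))
    }
  }
  n <- cfg$n_classes

  n_missing <- floor(cfg$missing_text_fraction * n)
  if (n_missing > 0L) {
    cand <- setdiff(seq_len(n), 1L)  # the root keeps its definition
    drop_idx <- cand[sample.int(length(cand), min(n_missing, length(cand)))]
    defs[drop_idx] <- ""
  }

  rel_types <- c("related_to", "part_of", "participates_in")
  existing <- paste(pmin(edges_from, edges_to), pmax(edges_from, edges_to))
  added <- 0L; tries <- 0L
  while (added < cfg$n_relations && tries < 50L * max(1L, cfg$n_relations)) {
    tries <- tries + 1L
    uv <- sample.int(n, 2L)
    key <- paste(min(uv), max(uv))
    if (key %in% existing) next
    existing <- c(existing, key)
    edges_from <- c(edges_from, uv[1])
    edges_to <- c(edges_to, uv[2])
    edges_rel <- c(edges_rel, rel_types[(added %% length(rel_types)) + 1L])
    added <- added + 1L
  }

  vertices <- tibble(
    id = id_of(seq_len(n)),
    label = sprintf("concept %d", seq_len(n)),
    definition = defs,
    text = NA_character_,
    text_source = NA_character_
  )
  graph <- structure(
    list(vertices = vertices,
         edges = tibble(from = id_of(edges_from), to = id_of(edges_to),
                        relation = edges_rel)),
    class = "ontology_graph"
  )
  graph <- resolve_texts(graph)
  attr(graph, "ground_truth") <- list(
    duplicates = tibble(dup = id_of(n_base + seq_len(n_dup)),
                        orig = id_of(dup_of)),
    topics = setNames(topic, id_of(seq_len(n_base))),
    config = cfg
  )
  graph
}

#' Export a class graph as OWL Turtle
#'
#' Writes classes, labels, definition annotations (omitted for classes with
#' an empty definition), `subClassOf` axioms and object-property
#' assertions; every non-`subClassOf` relation label is declared as an
#' `owl:ObjectProperty`. The output round-trips through [read_ontology()]
#' and [as_ontology_graph()] to an isomorphic graph.
#'
#' @param graph An `ontology_graph`.
#' @param path Output `.ttl` path.
#' @export
write_ontology_ttl <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  esc <- function(x) gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x))
  lit <- function(x) paste0("\"", esc(x), "\"")
  lines <- c(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix obo: <http://purl.obolibrary.org/obo/> .",
    ""
  )
  rels <- setdiff(unique(graph$edges$relation), "subClassOf")
  ns <- "http://example.org/synthetic#"
  for (r in rels) {
    lines <- c(lines, paste0("<", ns, r, "> a owl:ObjectProperty ; rdfs:label ",
                             lit(gsub("_", " ", r)), " ."))
  }
  v <- graph$vertices
  e <- graph$edges
  for (i in seq_len(nrow(v))) {
    stmt <- paste0("<", v$id[i], "> a owl:Class ; rdfs:label ", lit(v$label[i]))
    if (!is.na(v$definition[i]) && nzchar(v$definition[i])) {
      stmt <- paste0(stmt, " ; obo:IAO_0000115 ", lit(v$definition[i]))
    }
    parents <- e$to[e$relation == "subClassOf" & e$from == v$id[i]]
    for (p in parents) stmt <- paste0(stmt, " ; rdfs:subClassOf <", p, ">")
    lines <- c(lines, paste0(stmt, " ."))
  }
  rel_rows <- e[e$relation != "subClassOf", ]
  for (i in seq_len(nrow(rel_rows))) {
    lines <- c(lines, paste0("<", rel_rows$from[i], "> <", ns,
                             rel_rows$relation[i], "> <", rel_rows$to[i], "> ."))
  }
  writeLines(lines, path)
  invisible(graph)
}
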