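#' Build the class graph from a raw triple set
#'
#' Projects an ontology onto a simple undirected graph of classes. Under the
#' default edge policy, `rdfs:subClassOf` axioms and object-property
#' assertions between two declared classes become edges; annotation- and
#' data-property triples never do. Self-loops and duplicate (unordered)
#' edges are dropped, with the dropped counts reported via a message and
#' kept as attributes.
#'
#' @param raw An `ontropy_raw` object from [read_ontology()].
#' @param edge_policy A list with logical elements `subclassof` and
#'   `object_properties`, and optionally `extra_predicates`, a character
#'   vector of additional predicate IRIs to treat as edges.
#' @return An `ontology_graph`: a list with `vertices`, a tibble
#'   (`id`, `label`, `definition`, `text`, `text_source`), and `edges`, a
#'   tibble (`from`, `to`, `relation`); `subClassOf` edges run child ->
#'   parent in `from`/`to`, but all edges are undirected for connectivity
#'   purposes. Attributes `dropped_self_loops` and `dropped_duplicates`
#'   carry the cleanup counts.
#' @export
as_ontology_graph <- function(raw,
                              edge_policy = list(subclassof = TRUE,
                                                 object_properties = TRUE)) {
  stopifnot(inherits(raw, "ontropy_raw"))
  tr <- raw$triples
  policy <- utils::modifyList(
    list(subclassof = TRUE, object_properties = TRUE,
         extra_predicates = character()),
    edge_policy
  )

  classes <- unique(tr$subject[tr$predicate == IRI$type & tr$object == IRI$class])
  obj_props <- unique(tr$subject[tr$predicate == IRI$type & tr$object == IRI$objprop])

  edge_rows <- tr[FALSE, ]
  if (isTRUE(policy$subclassof)) {
    sc <- tr[tr$predicate == IRI$subclassof & tr$object_type == "iri", ]
    edge_rows <- rbind(edge_rows, sc)
  }
  rel_preds <- policy$extra_predicates
  if (isTRUE(policy$object_properties)) rel_preds <- union(rel_preds, obj_props)
  if (length(rel_preds) > 0L) {
    op <- tr[tr$predicate %in% rel_preds & tr$object_type == "iri" &
               tr$subject %in% classes & tr$object %in% classes, ]
    edge_rows <- rbind(edge_rows, op)
  }

  edges <- tibble(
    from = edge_rows$subject,
    to = edge_rows$object,
    relation = ifelse(edge_rows$predicate == IRI$subclassof,
                      "subClassOf", iri_local(edge_rows$predicate))
  )
  n0 <- nrow(edges)
  edges <- edges[edges$from != edges$to, ]
  n_loops <- n0 - nrow(edges)
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- edges[!dup, ]
  if (n_loops + n_dup > 0L) {
    inform(paste0("as_ontology_graph: dropped ", n_loops, " self-loop(s) and ",
                  n_dup, " duplicate edge(s)"))
  }

  ids <- union(classes, union(edges$from, edges$to))
  labels <- literal_map(tr, IRI$label)
  defs <- literal_map(tr, IRI$definition)
  vertices <- tibble(
    id = sort(ids),
    label = unname(labels[sort(ids)]),
    definition = unname(defs[sort(ids)])
  )
  vertices$label[is.na(vertices$label)] <- iri_local(vertices$id[is.na(vertices$label)])
  vertices$definition[is.na(vertices$definition)] <- ""
  vertices$text <- NA_character_
  vertices$text_source <- NA_character_

  structure(
    list(vertices = vertices, edges = edges),
    class = "ontology_graph",
    dropped_self_loops = n_loops,
    dropped_duplicates = n_dup
  )
}

# first literal value per subject for a given predicate
literal_map <- function(tr, pred) {
  rows <- tr[tr$predicate == pred & tr$object_type == "literal", ]
  rows <- rows[!duplicated(rows$subject), ]
  setNames(rows$object, rows$subject)
}

iri_local <- function(x) sub("^.*[#/]", "", x)

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", nrow(x$vertices), " classes, ",
      nrow(x$edges), " edges", sep = "")
  if (!all(is.na(x$vertices$text_source))) {
    cat(" (texts resolved)")
  }
  cat("\n")
  invisible(x)
}

#' Convert a class graph to an igraph object
#'
#' @param graph An `ontology_graph`.
#' @return An undirected simple [igraph::graph] whose vertex names are the
#'   class ids.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  igraph::graph_from_data_frame(
    d = graph$edges[, c("from", "to")],
    directed = FALSE,
    vertices = graph$vertices[, "id", drop = FALSE]
  )
}

#' Resolve a text description for every class
#'
#' Applies the fallback cascade used before text embedding: a class keeps its
#' own textual definition if it has one; otherwise an injected external text
#' source is queried with the class label (at most `max_hook_sentences`
#' sentences are kept); otherwise the class copies the resolved description
#' of its described superclass(es), propagating bottom-up along
#' `subClassOf` until a described ancestor is found (ties between multiple
#' described parents are broken by concatenating their texts in
#' lexicographic id order); otherwise the class label itself is adopted.
#' All resolved texts are lowercased token sequences stored as
#' space-separated strings.
#'
#' @param graph An `ontology_graph`.
#' @param external_hook Optional function `function(label)` returning a
#'   character vector of sentences (or `NULL`/empty when nothing is found).
#'   Injected rather than fetched live so that runs are reproducible.
#' @param max_hook_sentences Maximum number of hook sentences retained
#'   (default 5).
#' @return The graph with `text` and `text_source` filled for every vertex;
#'   `text_source` is one of `"definition"`, `"external-hook"`,
#'   `"superclass-copy"`, `"label-fallback"`. Re-applying the function is a
#'   no-op.
#' @export
resolve_texts <- function(graph, external_hook = NULL, max_hook_sentences = 5L) {
  stopifnot(inherits(graph, "ontology_graph"))
  v <- graph$vertices
  n <- nrow(v)
  if (n == 0L) return(graph)
  text <- rep(NA_character_, n)
  src <- rep(NA_character_, n)
  names(text) <- names(src) <- v$id

  has_def <- nzchar(v$definition) & vapply(tokenize_text(v$definition), length, 1L) > 0L
  text[has_def] <- normalize_text(v$definition[has_def])
  src[has_def] <- "definition"

  if (!is.null(external_hook)) {
    for (k in which(is.na(src))) {
      sentences <- external_hook(v$label[k])
      if (length(sentences) > 0L && any(nzchar(sentences))) {
        sentences <- head(sentences[nzchar(sentences)], max_hook_sentences)
        t <- normalize_text(paste(sentences, collapse = " "))
        if (nzchar(t)) {
          text[k] <- t
          src[k] <- "external-hook"
        }
      }
    }
  }

  # bottom-up superclass copy, iterated to propagate transitively
  sc <- graph$edges[graph$edges$relation == "subClassOf", c("from", "to")]
  repeat {
    changed <- FALSE
    for (k in which(is.na(src))) {
      parents <- sort(sc$to[sc$from == v$id[k]])
      described <- parents[!is.na(src[parents]) &
                             src[parents] %in% c("definition", "external-hook",
                                                 "superclass-copy")]
      if (length(described) > 0L) {
        text[k] <- paste(text[described], collapse = " ")
        src[k] <- "superclass-copy"
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  for (k in which(is.na(src))) {
    t <- normalize_text(v$label[k])
    if (nzchar(t)) {
      text[k] <- t
      src[k] <- "label-fallback"
    }
  }

  if (anyNA(src)) {
    abort(paste0("no text description resolvable for class(es): ",
                 paste(v$id[is.na(src)], collapse = ", ")),
          class = "ontropy_text_error")
  }
  graph$vertices$text <- unname(text)
  graph$vertices$text_source <- unname(src)
  graph
}
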