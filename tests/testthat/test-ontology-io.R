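test_that("the three dialect readers agree on identical content", {
  raw_xml <- read_ontology(toy_rdfxml())
  raw_ttl <- read_ontology(toy_turtle())
  raw_obo <- read_ontology(toy_obo())

  expect_identical(triple_key(raw_xml), triple_key(raw_ttl))
  expect_identical(triple_key(raw_xml), triple_key(raw_obo))
  expect_equal(sum(raw_xml$triples$predicate ==
                     "http://www.w3.org/2000/01/rdf-schema#subClassOf"), 2L)
  # annotation literals preserved verbatim
  defs <- raw_ttl$triples$object[raw_ttl$triples$predicate ==
                                   "http://purl.obolibrary.org/obo/IAO_0000115"]
  expect_identical(defs, "a viral process")
})

test_that("empty but valid documents parse to zero triples", {
  p <- write_fixture(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"/>'
  ), ".owl")
  expect_equal(nrow(read_ontology(p)$triples), 0L)
  p2 <- write_fixture("@prefix owl: <http://www.w3.org/2002/07/owl#> .", ".ttl")
  expect_equal(nrow(read_ontology(p2)$triples), 0L)
})

test_that("parse failures name the dialect and position", {
  bad <- write_fixture(c(
    "@prefix : <http://ex.org/> .",
    ":A :rel"  # missing object and terminator
  ), ".ttl")
  expect_error(read_ontology(bad), "line", class = "ontropy_dialect_error")
  expect_error(read_ontology(write_fixture("<unclosed", ".owl")),
               class = "ontropy_dialect_error")
  expect_error(read_ontology(write_fixture("x", ".xyz")),
               class = "ontropy_config_error")
})

test_that("graph construction follows the simple-graph rules", {
  g <- as_ontology_graph(read_ontology(toy_turtle()))
  expect_equal(nrow(g$vertices), 3L)
  expect_equal(nrow(g$edges), 2L)

  # self-loop and duplicate assertions are dropped with a logged count
  ttl <- write_fixture(c(
    '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .',
    '@prefix owl: <http://www.w3.org/2002/07/owl#> .',
    '@prefix : <http://ex.org/o#> .',
    ':A a owl:Class ; rdfs:subClassOf :A .',
    ':B a owl:Class ; rdfs:subClassOf :A .',
    ':B rdfs:subClassOf :A .'
  ), ".ttl")
  expect_message(g2 <- as_ontology_graph(read_ontology(ttl)),
                 "1 self-loop.*1 duplicate")
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(attr(g2, "dropped_self_loops"), 1L)

  # adjacency is symmetric with a zero diagonal
  C <- connectivity_matrix(g, mode = "adjacency")
  expect_identical(C, t(C))
  expect_true(all(diag(C) == 0))

  # annotation/data property triples never become edges
  ttl3 <- write_fixture(c(
    '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .',
    '@prefix owl: <http://www.w3.org/2002/07/owl#> .',
    '@prefix : <http://ex.org/o#> .',
    ':A a owl:Class . :B a owl:Class .',
    ':note a owl:AnnotationProperty .',
    ':A :note :B .'
  ), ".ttl")
  expect_equal(nrow(as_ontology_graph(read_ontology(ttl3))$edges), 0L)
})

test_that("text fallback cascade resolves every class", {
  # child with no definition copies its parent's text, transitively
  g <- make_graph(rbind(c("child", "mid"), c("mid", "parent")),
                  texts = c("", "", "a viral process"))
  v <- g$vertices
  expect_equal(v$text[v$id == "child"], "a viral process")
  expect_equal(v$text_source[v$id == "child"], "superclass-copy")
  expect_equal(v$text_source[v$id == "mid"], "superclass-copy")
  expect_equal(v$text_source[v$id == "parent"], "definition")

  # vertex with its own definition is untouched
  expect_equal(v$text[v$id == "parent"], "a viral process")

  # external hook is preferred over superclass copy, capped at 5 sentences
  hook <- function(label) paste("sentence", 1:8, "about", label)
  g2 <- make_graph(rbind(c("child", "parent")), texts = c("", "x y z"))
  g2$vertices$text <- NA_character_; g2$vertices$text_source <- NA_character_
  g2 <- resolve_texts(g2, external_hook = hook)
  child <- g2$vertices[g2$vertices$id == "child", ]
  expect_equal(child$text_source, "external-hook")
  expect_equal(sum(strsplit(child$text, " ")[[1]] == "sentence"), 5L)

  # orphan with only a label falls back to the tokenized label
  g3 <- make_graph(rbind(c("A", "B")), texts = c("", ""))
  expect_true(all(g3$vertices$text_source == "label-fallback"))
  expect_equal(g3$vertices$text[g3$vertices$id == "A"], "a")

  # ties: multiple described parents concatenate in lexicographic id order
  g4 <- make_graph(rbind(c("kid", "P2"), c("kid", "P1")),
                   ids = c("P1", "P2", "kid"),
                   texts = c("first parent", "second parent", ""))
  expect_equal(g4$vertices$text[g4$vertices$id == "kid"],
               "first parent second parent")

  # nothing to fall back on at all -> hard error naming the vertex
  bad <- structure(list(
    vertices = tibble::tibble(id = "N1", label = "", definition = "",
                              text = NA_character_, text_source = NA_character_),
    edges = tibble::tibble(from = character(), to = character(),
                           relation = character())
  ), class = "ontology_graph")
  expect_error(resolve_texts(bad), "N1", class = "ontropy_text_error")
})

test_that("resolve_texts is idempotent and tokens are lowercase", {
  g <- make_graph(rbind(c("B", "A"), c("C", "B")),
                  texts = c("A Viral PROCESS!", "", ""))
  expect_identical(resolve_texts(g), g)
  expect_true(all(grepl("^[a-z0-9 ]+$", g$vertices$text)))
})

test_that("summary statistics count distinct declarations", {
  ttl <- write_fixture(c(
    '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .',
    '@prefix owl: <http://www.w3.org/2002/07/owl#> .',
    '@prefix : <http://ex.org/o#> .',
    ':A a owl:Class . :B a owl:Class . :C a owl:Class .',
    ':B rdfs:subClassOf :A . :C rdfs:subClassOf :A .',
    ':A owl:equivalentClass :B .',
    ':p1 a owl:ObjectProperty . :p2 a owl:ObjectProperty .',
    ':q a owl:AnnotationProperty .',
    ':A rdfs:label "alpha" .'
  ), ".ttl")
  st <- ontology_stats(read_ontology(ttl))
  expect_equal(st$n_classes, 3L)
  expect_equal(st$n_subclassof, 2L)
  expect_equal(st$n_equivalent, 1L)
  expect_equal(st$n_object_properties, 2L)
  expect_equal(st$n_annotation_properties, 1L)
  expect_equal(st$n_data_properties, 0L)
  expect_equal(st$n_triples_with_annotation, 1L)  # the one label literal

  empty <- read_ontology(write_fixture(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .", ".ttl"))
  expect_true(all(as.numeric(ontology_stats(empty)) == 0))
})

test_that("statistics are additive over disjoint ontologies", {
  r1 <- read_ontology(toy_turtle())
  ttl2 <- write_fixture(c(
    '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .',
    '@prefix owl: <http://www.w3.org/2002/07/owl#> .',
    '@prefix : <http://other.org/x#> .',
    ':X a owl:Class . :Y a owl:Class . :Y rdfs:subClassOf :X .',
    ':r a owl:ObjectProperty .'
  ), ".ttl")
  r2 <- read_ontology(ttl2)
  combined <- r1
  combined$triples <- rbind(r1$triples, r2$triples)
  expect_equal(as.numeric(ontology_stats(combined)),
               as.numeric(ontology_stats(r1)) + as.numeric(ontology_stats(r2)))
})

test_that("granularity counts distinct properties per normalized label", {
  ttl <- write_fixture(c(
    '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .',
    '@prefix owl: <http://www.w3.org/2002/07/owl#> .',
    '@prefix : <http://ex.org/o#> .',
    ':author a owl:ObjectProperty ; rdfs:label "Creator" .',
    ':director a owl:ObjectProperty ; rdfs:label "creator" .',
    ':created a owl:ObjectProperty ; rdfs:label "created" .'
  ), ".ttl")
  gr <- ontology_granularity(read_ontology(ttl))
  expect_equal(gr$n_properties[gr$label == "creator"], 2L)
  expect_equal(gr$n_properties[gr$label == "created"], 1L)
  expect_true(all(gr$n_properties >= 1L))

  none <- read_ontology(toy_turtle())
  expect_equal(nrow(ontology_granularity(none)), 0L)
})

test_that("the edge-list exchange format round-trips the graph", {
  g <- suppressMessages(resolve_texts(as_ontology_graph(read_ontology(toy_turtle()))))
  ep <- tempfile(); vp <- tempfile()
  write_ontology_graph(g, ep, vp)
  g2 <- read_ontology_graph(ep, vp)
  expect_identical(sort(g$vertices$id), sort(g2$vertices$id))
  expect_identical(edge_key(g), edge_key(g2))
  expect_identical(g$vertices$text, g2$vertices$text)
})
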