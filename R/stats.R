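#' Summary statistics of an ontology
#'
#' Counts the constructs commonly tabulated when ontologies are compared:
#' triples carrying annotation/data (here: triples whose object is a
#' literal), plain structural triples, declared classes, `subClassOf`
#' axioms, equivalent- and disjoint-class axioms, and the three property
#' kinds (`owl:ObjectProperty`, `owl:AnnotationProperty`,
#' `owl:DatatypeProperty`). Each counter counts distinct declarations.
#'
#' @param raw An `ontropy_raw` object.
#' @return A one-row tibble with columns `n_triples_with_annotation`,
#'   `n_triples_without_annotation`, `n_classes`, `n_subclassof`,
#'   `n_equivalent`, `n_disjoint`, `n_object_properties`,
#'   `n_annotation_properties`, `n_data_properties`.
#' @export
ontology_stats <- function(raw) {
  stopifnot(inherits(raw, "ontropy_raw"))
  tr <- unique(raw$triples)
  typed <- function(cls) {
    length(unique(tr$subject[tr$predicate == IRI$type & tr$object == cls]))
  }
  tibble(
    n_triples_with_annotation = sum(tr$object_type == "literal"),
    n_triples_without_annotation = sum(tr$object_type != "literal"),
    n_classes = typed(IRI$class),
    n_subclassof = sum(tr$predicate == IRI$subclassof),
    n_equivalent = sum(tr$predicate == IRI$equivalent),
    n_disjoint = sum(tr$predicate == IRI$disjoint),
    n_object_properties = typed(IRI$objprop),
    n_annotation_properties = typed(IRI$annprop),
    n_data_properties = typed(IRI$dataprop)
  )
}

#' Granularity profile of an ontology
#'
#' Estimates semantic granularity by counting, for each normalized property
#' label, how many distinct properties carry it: a vocabulary that splits
#' one notion (say "creator") across several properties is finer-grained
#' than one with a single property for it. A property's label is its
#' `rdfs:label` when present, otherwise the local name of its IRI.
#' Normalization lowercases and collapses non-alphanumeric runs.
#'
#' @param raw An `ontropy_raw` object.
#' @return A tibble with columns `label` and `n_properties` (each count
#'   >= 1), sorted by decreasing count then label. Empty when the ontology
#'   declares no properties.
#' @export
ontology_granularity <- function(raw) {
  stopifnot(inherits(raw, "ontropy_raw"))
  tr <- raw$triples
  props <- unique(tr$subject[tr$predicate == IRI$type &
                               tr$object %in% c(IRI$objprop, IRI$annprop,
                                                IRI$dataprop)])
  if (length(props) == 0L) {
    return(tibble(label = character(), n_properties = integer()))
  }
  labels <- literal_map(tr, IRI$label)
  raw_label <- ifelse(props %in% names(labels), labels[props],
                      gsub("[_-]+", " ", iri_local(props)))
  norm <- normalize_text(raw_label)
  counts <- table(norm)
  out <- tibble(label = names(counts), n_properties = as.integer(counts))
  out[order(-out$n_properties, out$label), ]
}
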