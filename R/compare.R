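#' Softmax aspect scores across compared ontologies
#'
#' Scores each ontology on three aspects of data quantity — total triples,
#' classes/entities, and relations (the three property kinds) — by
#' softmax-normalizing the counts over the compared set, so each aspect's
#' scores lie in (0, 1) and sum to 1. Counts are log-transformed
#' (`log1p`) before the softmax: raw ontology counts span orders of
#' magnitude and would saturate the softmax to a one-hot vector.
#'
#' @param stats A tibble with an `ontology` column and the columns of
#'   [ontology_stats()], one row per ontology (at least 2 rows).
#' @return A tibble with columns `ontology`, `aspect`, `count`, `score`.
#' @export
aspect_scores <- function(stats) {
  stopifnot(is.data.frame(stats), "ontology" %in% names(stats))
  if (nrow(stats) < 2L) {
    abort("aspect_scores: need at least 2 ontologies to compare",
          class = "ontropy_config_error")
  }
  counts <- tibble(
    ontology = rep(stats$ontology, 3L),
    aspect = rep(c("triples", "classes_entities", "relations"),
                 each = nrow(stats)),
    count = c(stats$n_triples_with_annotation + stats$n_triples_without_annotation,
              stats$n_classes,
              stats$n_object_properties + stats$n_annotation_properties +
                stats$n_data_properties)
  )
  counts |>
    dplyr::group_by(.data$aspect) |>
    dplyr::mutate(score = softmax(log1p(.data$count))) |>
    dplyr::ungroup()
}

#' Geometric-mean aggregate of aspect scores
#'
#' Aggregates one ontology's aspect scores into a single score by geometric
#' mean — chosen over the arithmetic mean because it penalises imbalance:
#' the greater the spread across aspects, the smaller the mean.
#'
#' @param scores A positive numeric vector (typically the three aspect
#'   scores of one ontology).
#' @return The geometric mean (scalar).
#' @export
aggregate_score <- function(scores) {
  stopifnot(is.numeric(scores), length(scores) >= 1L)
  if (any(scores <= 0)) {
    abort("aggregate_score: all aspect scores must be positive",
          class = "ontropy_config_error")
  }
  exp(mean(log(scores)))
}

#' Correlate entropy values with aggregate statistic scores
#'
#' Pearson product-moment and Spearman rank correlation between
#' per-ontology entropy values and per-ontology aggregate scores, matched
#' by name.
#'
#' @param entropies Named numeric vector of entropy values.
#' @param aggregates Named numeric vector of aggregate scores (same names).
#' @return A tibble with columns `method` and `estimate`.
#' @export
entropy_correlation <- function(entropies, aggregates) {
  stopifnot(!is.null(names(entropies)), !is.null(names(aggregates)))
  common <- intersect(names(entropies), names(aggregates))
  if (length(common) < 3L) {
    abort("entropy_correlation: need at least 3 paired ontologies",
          class = "ontropy_config_error")
  }
  x <- entropies[common]; y <- aggregates[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("entropy_correlation: zero variance; correlation undefined",
          class = "ontropy_degenerate_error")
  }
  tibble(
    method = c("pearson", "spearman"),
    estimate = c(cor(x, y, method = "pearson"),
                 cor(x, y, method = "spearman"))
  )
}

#' Multi-ontology comparison report
#'
#' Combines aspect scores, geometric-mean aggregates, entropy values
#' (full and optionally text-ablated) and the entropy/statistics
#' correlations into one report. The correlation relates each ontology's
#' entropy to its aggregate statistic score across the compared set.
#'
#' @param stats As in [aspect_scores()].
#' @param entropies Named numeric vector of EAPB entropies (names matching
#'   `stats$ontology`).
#' @param entropies_ablated Optional named vector of text-ablated entropies.
#' @return A `comparison_report`: list with `aspects`, `aggregates`,
#'   `entropies` and (when >= 3 ontologies) `correlation` tibbles.
#' @export
compare_ontologies <- function(stats, entropies, entropies_ablated = NULL) {
  asp <- aspect_scores(stats)
  agg <- asp |>
    dplyr::group_by(.data$ontology) |>
    dplyr::summarise(aggregate = aggregate_score(.data$score), .groups = "drop")
  ent <- tibble(
    ontology = names(entropies),
    entropy = unname(entropies),
    entropy_ablated = if (is.null(entropies_ablated)) NA_real_
                      else unname(entropies_ablated[names(entropies)])
  )
  correlation <- NULL
  if (length(entropies) >= 3L) {
    aggv <- setNames(agg$aggregate, agg$ontology)
    correlation <- tryCatch(entropy_correlation(entropies, aggv),
                            ontropy_degenerate_error = function(e) NULL)
  }
  structure(list(aspects = asp, aggregates = agg, entropies = ent,
                 correlation = correlation),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", nrow(x$aggregates), " ontologies\n", sep = "")
  print(dplyr::left_join(x$aggregates, x$entropies, by = "ontology"))
  if (!is.null(x$correlation)) {
    cat("entropy vs aggregate statistics:\n")
    print(x$correlation)
  }
  invisible(x)
}
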