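#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an entropy report
#'
#' @param x An `entropy_report`.
#' @param ... Unused.
#' @return A tibble with one row per concept: `id`, `p_prime`,
#'   `contribution_bits`.
#' @export
tidy.entropy_report <- function(x, ...) {
  x$contributions
}

#' @rdname tidy.entropy_report
#' @return For `glance()`: a one-row tibble summarising the report.
#' @export
glance.entropy_report <- function(x, ...) {
  tibble(
    s_prime = x$s_prime,
    baseline_entropy = x$baseline_entropy,
    max_entropy = log2(x$n_vertices),
    n_vertices = x$n_vertices,
    connectivity_mode = x$connectivity_mode,
    similarity_mode = x$similarity_mode
  )
}

#' Tidy a trained embedding model
#'
#' @param x An `ontropy_model`.
#' @param ... Unused.
#' @return A tibble of the per-epoch objective (`epoch`, `objective`),
#'   with epoch 0 holding the pre-training value.
#' @export
tidy.ontropy_model <- function(x, ...) {
  tibble(
    epoch = c(0L, seq_along(x$loss_history)),
    objective = c(x$initial_objective, x$loss_history)
  )
}

#' @rdname tidy.ontropy_model
#' @export
glance.ontropy_model <- function(x, ...) {
  tibble(
    n_vertices = length(x$ids),
    n_edges = nrow(x$graph$edges),
    dim = x$dim,
    vocab_size = length(x$vocab),
    epochs = length(x$loss_history),
    initial_objective = x$initial_objective,
    final_objective = tail(x$loss_history, 1)
  )
}

#' Plot the per-concept entropy contributions
#'
#' Bar chart of the largest per-concept contributions `-P'_k log2 P'_k`,
#' which localise where the ontology's connectivity mass concentrates.
#'
#' @param object An `entropy_report`.
#' @param top_n Number of concepts shown (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.entropy_report <- function(object, top_n = 20L, ...) {
  df <- object$contributions |>
    dplyr::arrange(dplyr::desc(.data$contribution_bits)) |>
    head(top_n)
  df$id <- factor(iri_local(df$id), levels = rev(iri_local(df$id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contribution_bits, y = .data$id)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "contribution to S' (bits)", y = NULL,
      title = sprintf("S' = %.4f bits (%s, %s)", object$s_prime,
                      object$connectivity_mode, object$similarity_mode)
    )
}

#' Plot the training objective trajectory
#'
#' @param object An `ontropy_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ontropy_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean per-edge objective",
                  title = "Joint embedding objective")
}
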