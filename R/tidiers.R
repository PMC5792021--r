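#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training history of a fitted model
#'
#' @param x A `trained_model`.
#' @param ... Unused.
#' @return A tibble with one row per validation point: `iteration`,
#'   `train_loss`, `val_accuracy`.
#' @export
tidy.trained_model <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted model
#'
#' @param x A `trained_model`.
#' @param ... Unused.
#' @return A one-row tibble: `regime`, `view`, `n_labels`, `iterations`,
#'   `best_iteration`, `best_val_accuracy`.
#' @export
glance.trained_model <- function(x, ...) {
  tibble::tibble(
    regime = x$regime,
    view = x$view %||% NA_character_,
    n_labels = x$architecture$n_labels,
    iterations = x$provenance$hyperparams$iterations,
    best_iteration = x$best_iteration,
    best_val_accuracy = x$best_accuracy
  )
}

#' Plot a training history
#'
#' Training loss and validation top-1 accuracy against the iteration
#' counter, with the selected checkpoint marked.
#'
#' @param object A `trained_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trained_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_accuracy"),
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$best_iteration,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = paste("Training history:", object$regime,
                                object$view %||% ""))
}

#' Plot a metrics report
#'
#' Accuracy, average precision and minimum precision against the top-list
#' size t, one line per classifier/ensemble when the report carries an
#' identifying column.
#'
#' @param object A [metrics_report()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  id_col <- intersect(c("ensemble", "regime"), names(object))[1]
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object),
                  -dplyr::any_of("label_precision")),
    c("accuracy", "average_precision", "minimum_precision"),
    names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value))
  if (!is.na(id_col)) {
    p <- p + ggplot2::aes(colour = .data[[id_col]],
                          group = .data[[id_col]]) +
      ggplot2::geom_line()
  } else {
    p <- p + ggplot2::geom_line(group = 1)
  }
  p + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_x_continuous(breaks = unique(long$t)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "top-t list size", y = NULL)
}

#' Plot a diversity report
#'
#' Pairwise both-correct / only-one-correct / both-fault shares per member
#' pair, stacked; the bar total for `bc + oc + df` is 1 by the diversity
#' identity.
#'
#' @param object A [ensemble_diversity()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diversity_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object),
                  pair = paste(.data$member_a, .data$member_b, sep = " / ")),
    c("bc", "oc", "df"), names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure, levels = c("df", "oc", "bc"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pair, y = .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "share of samples",
                  fill = NULL)
}
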