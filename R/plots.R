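#' Plot methods
#'
#' `autoplot()` methods give each result type a default ggplot2 view:
#' * `sympl_kb` — the alias-count distribution over concepts (the long tail
#'   motivating rare-concept augmentation);
#' * `sympl_linking` — mentions per pipeline stage, split by correctness when
#'   gold codes are present;
#' * `sympl_eval` — precision / recall / F1 bars;
#' * `sympl_grid_search` — accuracy over the weight simplex, projected onto
#'   (w_full, w_head).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name symplink-autoplot
NULL

#' @rdname symplink-autoplot
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_bar geom_tile labs
#'   scale_fill_viridis_c theme_minimal
#' @exportS3Method ggplot2::autoplot
autoplot.sympl_kb <- function(object, ...) {
  counts <- kb_alias_counts(object) |> count(.data$n_aliases, name = "n_concepts")
  ggplot(counts, aes(x = factor(.data$n_aliases), y = .data$n_concepts)) +
    geom_col() +
    labs(
      x = "aliases per concept", y = "concepts",
      title = "Knowledge-base alias distribution"
    ) +
    theme_minimal()
}

#' @rdname symplink-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.sympl_linking <- function(object, ...) {
  df <- as_tibble(object)
  p <- if ("gold_code" %in% names(df)) {
    df$correct <- ifelse(df$code == df$gold_code, "correct", "wrong")
    ggplot(df, aes(x = .data$stage, fill = .data$correct)) +
      geom_bar()
  } else {
    ggplot(df, aes(x = .data$stage)) +
      geom_bar()
  }
  p + labs(
    x = "pipeline stage", y = "mentions",
    title = "Linking results by pipeline stage"
  ) + theme_minimal()
}

#' @rdname symplink-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.sympl_eval <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
      names_to = "metric", values_to = "value"
    )
  ggplot(df, aes(x = .data$metric, y = .data$value)) +
    geom_col() +
    labs(
      y = NULL, x = NULL,
      title = paste0("Span evaluation (", object$mode, " matching)")
    ) +
    theme_minimal()
}

#' @rdname symplink-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.sympl_grid_search <- function(object, ...) {
  ggplot(object$grid, aes(
    x = .data$w_full, y = .data$w_head, fill = .data$accuracy
  )) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(
      x = "w_full", y = "w_head",
      title = "Grid search over sliding-window weights"
    ) +
    theme_minimal()
}
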