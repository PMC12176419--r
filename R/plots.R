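#' Plot a condition dissimilarity matrix
#'
#' @param object a `mixsel_rdm`.
#' @param ... unused.
#' @return a ggplot heatmap.
#' @export
autoplot.mixsel_rdm <- function(object, ...) {
  df <- as_tibble(as.data.frame(as.table(unclass(object))),
                  .name_repair = ~ c("cond_a", "cond_b", "dissimilarity"))
  ggplot2::ggplot(df, ggplot2::aes(.data$cond_a, .data$cond_b,
                                   fill = .data$dissimilarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "dissimilarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a multidimensional-scaling embedding
#'
#' Conditions labeled `"category:task"` are colored by task and labeled by
#' category; other label schemes fall back to plain point labels.
#'
#' @param object a `mixsel_mds` tibble from [mds_embed()].
#' @param ... unused.
#' @return a ggplot scatter of the first two dimensions.
#' @export
autoplot.mixsel_mds <- function(object, ...) {
  df <- object
  parts <- strsplit(df$condition, ":", fixed = TRUE)
  if (all(lengths(parts) == 2)) {
    df$label <- vapply(parts, `[`, "", 1)
    df$group <- vapply(parts, `[`, "", 2)
  } else {
    df$label <- df$condition
    df$group <- "all"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   color = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-participant decoding accuracies
#'
#' @param object a tibble with `participant`, `accuracy` and optionally
#'   `task` columns (any of the decoding result tables).
#' @param chance reference line (.5 for two-class decoding).
#' @param ... unused.
#' @return a ggplot dot plot with the group mean.
#' @export
autoplot.mixsel_accuracy <- function(object, chance = 0.5, ...) {
  df <- as_tibble(object)
  df$x <- if ("task" %in% names(df)) df$task else df$region
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$accuracy)) +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          linewidth = 0.4, color = "firebrick") +
    ggplot2::labs(x = NULL, y = "decoding accuracy") +
    ggplot2::theme_minimal()
}

#' Mark a decoding result table for plotting
#'
#' Convenience: adds the `mixsel_accuracy` class so [ggplot2::autoplot()]
#' dispatches to the accuracy dot plot.
#'
#' @param tbl a result tibble with an `accuracy` column.
#' @return the same tibble, classed.
#' @export
as_accuracy_result <- function(tbl) {
  stopifnot("accuracy" %in% names(tbl))
  class(tbl) <- unique(c("mixsel_accuracy", class(tbl)))
  tbl
}
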