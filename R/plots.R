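#' @exportS3Method ggplot2::autoplot
#' @rdname species_grid
#' @param object A `species_grid`.
#' @param ... Unused.
autoplot.species_grid <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$values)) - 1L,
                           col = seq_len(ncol(object$values)) - 1L)
  df$code <- as.vector(t(object$values))
  df$species <- factor(ifelse(df$code == 0L, NA, df$code))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$species)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_discrete(na.value = "grey95", name = "species") +
    ggplot2::labs(title = paste("plot", object$plot_id), x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @exportS3Method ggplot2::autoplot
#' @rdname rlq
autoplot.rlq_fit <- function(object, type = c("plots", "species", "metrics",
                                              "traits"), ...) {
  type <- match.arg(type)
  m <- switch(type, plots = object$plot_scores,
              species = object$species_scores,
              metrics = object$metric_loadings,
              traits = object$trait_loadings)
  df <- matrix_to_tbl(m[, 1:min(2, ncol(m)), drop = FALSE], "label")
  if (ncol(df) < 3) df$axis2 <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                   label = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = paste0("axis 1 (", round(object$percent[1], 1), "%)"),
      y = if (length(object$percent) > 1)
        paste0("axis 2 (", round(object$percent[2], 1), "%)") else "axis 2",
      title = paste("RLQ", type)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
#' @rdname fourth_corner
autoplot.fourth_corner_fit <- function(object,
                                       alpha = c("sqrt05", "05"), ...) {
  alpha <- match.arg(alpha)
  df <- object$cells
  df$sig <- if (alpha == "sqrt05") df$sig_sqrt05 else df$sig_05
  df$assoc <- dplyr::case_when(
    df$sig & df$statistic > 0 ~ "positive",
    df$sig & df$statistic < 0 ~ "negative",
    TRUE ~ "none"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$trait,
                                   fill = .data$assoc)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(positive = "#c0392b",
                                          negative = "#2e60a0",
                                          none = "grey95"),
                               name = "association") +
    ggplot2::labs(title = paste0("fourth-corner associations (alpha = ",
                                 if (alpha == "sqrt05") "sqrt(0.05)" else "0.05",
                                 ")")) +
    ggplot2::theme_minimal()
}

#' Patch-size (or shape) distributions per species
#'
#' Histograms of a per-patch value faceted by species; patch sizes in this
#' kind of mosaic are typically strongly right-skewed while shape indices
#' are closer to symmetric.
#'
#' @param patches A [label_patches()] tibble.
#' @param value Column to plot (tidy-eval), default `area`.
#' @param min_patches Only species with at least this many patches are shown
#'   (default 30).
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_patch_distribution <- function(patches, value = area, min_patches = 30,
                                    bins = 30) {
  keep <- patches |>
    dplyr::count(.data$species_code) |>
    dplyr::filter(.data$n >= min_patches) |>
    dplyr::pull(.data$species_code)
  df <- dplyr::filter(patches, .data$species_code %in% keep)
  if (!nrow(df)) abort("no species reaches `min_patches` patches.")
  ggplot2::ggplot(df, ggplot2::aes(x = {{ value }})) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::facet_wrap(~species_code, scales = "free") +
    ggplot2::theme_minimal()
}

utils::globalVariables("area")
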