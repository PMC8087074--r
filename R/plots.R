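# ggplot2 methods for the result objects.

#' @export
autoplot.imcc_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble(x = seq(min(df$x), max(df$x), length.out = 200))
  a <- object$coefficients["a"]
  b <- object$coefficients["b"]
  grid$y <- switch(object$model_name,
    linear = a * grid$x + b,
    logarithmic = a * log(grid$x) + b,
    power = b * grid$x^a,
    exponential = b * exp(a * grid$x)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::labs(
      title = sprintf("%s fit, R² = %.3f", object$model_name,
                      object$r_squared),
      x = "score", y = "annotation similarity"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.imcc_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin, y = .data$relative)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::labs(x = "-log2(IMCC) interval", y = "relative frequency") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.modular_map <- function(object, ..., seed = 42) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(module = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  ed <- object$edges |>
    dplyr::left_join(nodes, by = c("module_x" = "module")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes, by = c("module_y" = "module")) |>
    dplyr::rename(x1 = "x", y1 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$imcc),
      colour = "grey60"
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 3, colour = "#b2182b") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$module),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = "IMCC")
}

#' Scatter of condition score distributions in principal component space
#'
#' @param pca A tibble from [pca_profiles()].
#' @return A ggplot.
#' @export
plot_pca_profiles <- function(pca) {
  ggplot2::ggplot(pca, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                    label = .data$condition)) +
    ggplot2::geom_point(size = 3, colour = "#2166ac") +
    ggplot2::geom_text(vjust = -1) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}
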