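#' Cube plot of library counts
#'
#' Renders the three-cycle count cube as cycle-1 x cycle-2 panels sliced
#' along cycle 3, so a family defined by a fixed cycle-3 building block (a
#' plane of the cube) fills a single panel.
#'
#' @param cube Output of [cube_coordinates()] (or a `del_counts` plus
#'   `schema` to compute it here).
#' @param schema Optional [del_schema()] when `cube` is a count table.
#' @param population Passed to [cube_coordinates()] when computing here.
#' @return A ggplot object.
#' @export
plot_cube <- function(cube, schema = NULL, population = NULL) {
  if (!is.null(schema)) cube <- cube_coordinates(cube, schema, population)
  ggplot2::ggplot(cube, ggplot2::aes(x = .data$index1, y = .data$index2)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$count, colour = .data$count),
                        alpha = 0.8) +
    ggplot2::facet_wrap(~index3, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_viridis_c(trans = "log10") +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "cycle 1 building block", y = "cycle 2 building block",
                  title = "Selection output by encoded building-block combination") +
    ggplot2::theme_minimal()
}

#' Stick plot of an analytic extension-product spectrum
#'
#' @param spectrum Output of [product_spectrum()].
#' @return A ggplot object: product probability against mass, coloured by
#'   stop/artifact class.
#' @export
plot_spectrum <- function(spectrum) {
  spectrum <- dplyr::mutate(
    spectrum,
    class = ifelse(is.na(.data$stopped_at), "full length",
                   paste0("stall@", .data$stopped_at, " (", .data$artifact, ")"))
  )
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$mass, y = .data$probability,
                               colour = .data$class)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mass, yend = 0),
                          linewidth = 1.2) +
    ggplot2::labs(x = "average mass (Da)", y = "probability",
                  title = "Primer-extension product spectrum") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_cube Autoplot method for enrichment results: fold
#'   enrichment against rank on a log scale.
#' @param object A `del_enrichment`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.del_enrichment <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$fold_enrichment)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "fold enrichment vs naive average") +
    ggplot2::theme_minimal()
}
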