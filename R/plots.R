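#' Ordination scatter plot of a PCoA result
#'
#' @param p A `pcoa_result`.
#' @param metadata Optional data.frame with `sample_id` plus grouping
#'   columns; rows are matched to the coordinate labels.
#' @param colour,shape Metadata columns mapped to colour / point shape.
#' @return A ggplot object (axis labels carry the proportion explained).
#' @export
plot_pcoa <- function(p, metadata = NULL, colour = "vent_field",
                      shape = "lifestyle") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_sym("ggplot2 is required for plotting")
  df <- data.frame(sample_id = rownames(p$coordinates), p$coordinates,
                   stringsAsFactors = FALSE)
  if (!is.null(metadata))
    df <- merge(df, metadata, by = "sample_id", sort = FALSE)
  aes_args <- list(x = as.name("Axis1"), y = as.name("Axis2"))
  if (!is.null(metadata) && colour %in% names(df))
    aes_args$colour <- as.name(colour)
  if (!is.null(metadata) && shape %in% names(df))
    aes_args$shape <- as.name(shape)
  ggplot2::ggplot(df, do.call(ggplot2::aes, aes_args)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%%)", 100 * p$proportion_explained[1]),
      y = sprintf("Axis 2 (%.1f%%)", 100 * p$proportion_explained[2])) +
    ggplot2::theme_minimal()
}
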