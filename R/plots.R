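#' Plot a sliding-window track
#'
#' Window values along the core genome with the genome-wide mean as a dashed
#' line; optional peak intervals are shaded.
#'
#' @param object A `"cf_track"` tibble.
#' @param peaks Optional peak tibble from [call_peaks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cf_track <- function(object, peaks = NULL, ...) {
  lab <- switch(attr(object, "stat") %||% "value",
                fst = expression(F[ST]), snp_count = "SNPs per window",
                "value")
  gg <- ggplot2::ggplot(object,
                        ggplot2::aes(x = (.data$start + .data$end) / 2,
                                     y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = mean(object$value, na.rm = TRUE),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "core genome position (bp)", y = lab) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = peaks, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      fill = "firebrick", alpha = 0.15)
  }
  gg
}

#' Plot growth curves coloured by clade
#'
#' @param growth Tidy growth table (`sample`, `condition`, `replicate`,
#'   `time_h`, `abs450`).
#' @param clades Clade assignment of samples.
#' @return A ggplot object faceted by condition.
#' @export
plot_growth_curves <- function(growth, clades) {
  cl <- as_clades(clades, unique(growth$sample), max_labels = NA)
  growth$clade <- unname(cl[growth$sample])
  ggplot2::ggplot(growth,
                  ggplot2::aes(x = .data$time_h, y = .data$abs450,
                               group = interaction(.data$sample,
                                                   .data$replicate),
                               colour = .data$clade)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "time (h)", y = "ABS450") +
    ggplot2::theme_minimal()
}

#' Heatmap of accessory-genome Jaccard similarity
#'
#' @param d Jaccard distance matrix from [jaccard_distances()].
#' @return A ggplot tile plot of `1 - d`.
#' @export
plot_jaccard_heatmap <- function(d) {
  s <- 1 - as.matrix(d)
  df <- as_tibble(as.data.frame(as.table(s), stringsAsFactors = FALSE))
  names(df) <- c("sample_i", "sample_j", "similarity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_i, y = .data$sample_j,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Jaccard\nsimilarity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
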