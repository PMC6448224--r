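#' Plot cell volumes by annotation zone
#'
#' @param object a `sam_atlas`.
#' @param ... unused.
#' @return A ggplot: boxplots of cell volume per zone.
#' @export
autoplot.sam_atlas <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$zone, y = .data$volume)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = expression(Cell ~ volume ~ (mu * m^3))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the distribution of shared interface areas
#'
#' When an annotation is supplied, interfaces are grouped by the zone pair
#' of their endpoint cells, mirroring the within-layer versus
#' between-layer comparisons used on real meristems.
#'
#' @param object a `cell_network`.
#' @param annotation optional annotation tibble (`label`, `zone`).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cell_network <- function(object, annotation = NULL, ...) {
  e <- object$edges
  if (!is.null(annotation)) {
    zmap <- setNames(annotation$zone, annotation$label)
    z1 <- zmap[as.character(e$from)]
    z2 <- zmap[as.character(e$to)]
    z1[is.na(z1)] <- "unassigned"
    z2[is.na(z2)] <- "unassigned"
    e$pair <- ifelse(z1 <= z2, paste(z1, z2, sep = "-"), paste(z2, z1, sep = "-"))
    ggplot2::ggplot(e, ggplot2::aes(x = .data$pair, y = .data$interface_area)) +
      ggplot2::geom_boxplot(outlier.size = 0.6) +
      ggplot2::labs(x = NULL, y = expression(Interface ~ area ~ (mu * m^2))) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  } else {
    ggplot2::ggplot(e, ggplot2::aes(x = .data$interface_area)) +
      ggplot2::geom_histogram(bins = 40) +
      ggplot2::labs(x = expression(Interface ~ area ~ (mu * m^2)), y = "Contacts") +
      ggplot2::theme_minimal()
  }
}

#' Plot anisotropy by zone
#'
#' @param atlas a `sam_atlas`.
#' @param anisotropy tibble from [cell_anisotropy()].
#' @return A ggplot: anisotropy distribution per zone.
#' @export
plot_anisotropy_by_zone <- function(atlas, anisotropy) {
  df <- dplyr::left_join(atlas$annotation,
                         dplyr::select(anisotropy, "label", "anisotropy"),
                         by = "label")
  ggplot2::ggplot(df[!is.na(df$anisotropy), ],
                  ggplot2::aes(x = .data$zone, y = .data$anisotropy)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 1 / 3, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "Anisotropy (1/3 = isotropic)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
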