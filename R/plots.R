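#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_tile
#'   scale_y_log10 labs theme_minimal scale_fill_viridis_c autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot the ranked intensity curve
#'
#' Per-peptide intensities in ascending order on a log axis, with extreme
#' calls highlighted when supplied.
#'
#' @param ranked a ranked curve from [rank_curve()].
#' @param extremes optional `pep_extremes` calls to highlight.
#' @return a ggplot.
#' @export
plot_rank_curve <- function(ranked, extremes = NULL) {
  p <- ggplot(ranked, aes(x = .data$rank, y = .data$intensity)) +
    geom_line(linewidth = 0.3, colour = "grey30") +
    scale_y_log10() +
    labs(x = "peptide rank (ascending adhesion)",
         y = "intensity (log scale)") +
    theme_minimal()
  if (!is.null(extremes) && nrow(extremes) > 0) {
    p <- p + geom_point(
      data = as_tibble(extremes),
      aes(colour = .data$side), size = 0.6
    ) + labs(colour = NULL)
  }
  p
}

#' Scatter plot of intensity against a property sum
#'
#' @param measurements per-peptide tibble with `peptide_id`, `intensity`.
#' @param profiles property tibble from [compute_property_profile()].
#' @param property property column to plot (e.g. `"SH"`).
#' @return a ggplot.
#' @export
plot_property_scatter <- function(measurements, profiles,
                                  property = "SH") {
  joined <- dplyr::inner_join(measurements[, c("peptide_id", "intensity")],
                              profiles, by = "peptide_id")
  ggplot(joined, aes(x = .data[[property]], y = .data$intensity)) +
    geom_point(alpha = 0.3, size = 0.5) +
    scale_y_log10() +
    labs(x = property, y = "intensity (log scale)") +
    theme_minimal()
}

#' Heatmap of a substitution matrix
#'
#' @param object a `pep_submatrix`.
#' @param ... unused.
#' @return a ggplot: positions on the y axis, residues on the x axis,
#'   cell fill = intensity; parent cells outlined.
#' @export
autoplot.pep_submatrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$residue, y = factor(.data$position))) +
    geom_tile(aes(fill = .data$intensity)) +
    geom_point(data = df[df$is_parent, ], shape = 0, size = 2) +
    scale_fill_viridis_c(na.value = "grey90") +
    labs(x = "substituted residue", y = "parent position",
         fill = "Int.") +
    theme_minimal()
}

#' Plot a per-protein window track
#'
#' @param object a `pep_track` (optionally flagged).
#' @param ... unused.
#' @return a ggplot of window intensity against window start, with
#'   flagged windows highlighted when present.
#' @export
autoplot.pep_track <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$start, y = .data$intensity)) +
    geom_line(colour = "grey40") +
    labs(x = "window start (residue)", y = "window Int.") +
    theme_minimal()
  if ("flagged" %in% names(df) && any(df$flagged, na.rm = TRUE)) {
    p <- p + geom_point(data = df[which(df$flagged), ],
                        colour = "firebrick", size = 1)
  }
  p
}
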