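# Basic visualization: RDM heatmaps (left/right hemisphere in the lower
# and upper triangle) and violin plots of per-subject averaged distances.
# Plotting is plumbing here, not a publication-figure reproduction.

#' Heatmap of one or two (hemisphere) RDMs
#'
#' With two matrices, the lower triangle shows the left-hemisphere RDM and
#' the upper triangle the right-hemisphere one, mirroring the conventional
#' two-hemisphere display; the diagonal (zero by construction) is blank.
#' Diverging palette: negative distances in blue, positive in red.
#'
#' @param rdm_lh `rdm` matrix (left hemisphere, lower triangle).
#' @param rdm_rh optional `rdm` (right hemisphere, upper triangle).
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_rdm <- function(rdm_lh, rdm_rh = NULL, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_rdm() requires ggplot2", call. = FALSE)
  d <- unclass(rdm_lh)
  if (!is.null(rdm_rh)) {
    stopifnot(all(dim(rdm_rh) == dim(d)))
    d[upper.tri(d)] <- unclass(rdm_rh)[upper.tri(rdm_rh)]
  }
  n <- nrow(d)
  df <- data.frame(
    i = factor(rep(rownames(d), n), levels = rev(rownames(d))),
    j = factor(rep(colnames(d), each = n), levels = colnames(d)),
    distance = as.vector(d))
  df$distance[as.integer(df$i) == n + 1L - as.integer(df$j)] <- NA
  lim <- max(abs(df$distance), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#1f6fb4", mid = "white",
                                  high = "#b2182b", limits = c(-lim, lim),
                                  na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "crossnobis\ndistance",
                  title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' Violin plot of per-subject averaged distances
#'
#' One violin per (region, selection) cell, split by region on the x axis,
#' with a zero reference line (the meaningful zero of the crossnobis
#' distance).
#'
#' @param distances subject-distance table (`region`, `selection`,
#'   `value`).
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_distance_violin <- function(distances, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_distance_violin() requires ggplot2", call. = FALSE)
  df <- distances[!is.na(distances$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$value,
                                   fill = .data$selection)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         scale = "width", alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "mean crossnobis distance", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
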