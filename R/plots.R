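# ggplot2 visualization: PCA scatter plots and Manhattan plots

MAX_PLOT_POINTS <- 200000
LOGP_CAP <- 300

#' @export
autoplot.invertype_pca <- function(object, labels = NULL, pcs = c(1, 2),
                                   ...) {
  check_components(object, pcs)
  df <- pc_scores(object, pcs)
  xvar <- paste0("PC", pcs[1]); yvar <- paste0("PC", pcs[2])
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, tibble::as_tibble(labels),
                           by = "sample_id")
    ggplot2::ggplot(df, ggplot2::aes(.data[[xvar]], .data[[yvar]],
                                     color = factor(.data$cluster))) +
      ggplot2::geom_point() +
      ggplot2::labs(x = paste("PC", pcs[1]), y = paste("PC", pcs[2]),
                    color = "cluster") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data[[xvar]], .data[[yvar]])) +
      ggplot2::geom_point() +
      ggplot2::labs(x = paste("PC", pcs[1]), y = paste("PC", pcs[2])) +
      ggplot2::theme_minimal()
  }
}

# deterministic thinning: above MAX_PLOT_POINTS SNPs, keep every
# ceil(n / MAX_PLOT_POINTS)-th point by position plus every point with
# -log10(p) >= 4
thin_track_points <- function(df, max_points = MAX_PLOT_POINTS) {
  n <- nrow(df)
  if (n <= max_points) return(df)
  stride <- ceiling(n / max_points)
  keep <- (seq_len(n) - 1L) %% stride == 0L | df$logp >= 4
  df[keep, , drop = FALSE]
}

#' @export
autoplot.assoc_track <- function(object, ...) {
  if (nrow(object) == 0L) abort("association track is empty")
  df <- tibble::tibble(
    pos_mb = object$pos / 1e6,
    logp = pmin(-log10(pmax(object$p_value, P_FLOOR)), LOGP_CAP))
  df <- thin_track_points(df)
  ggplot2::ggplot(df, ggplot2::aes(.data$pos_mb, .data$logp)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "Position (Mb)",
                  y = expression(-log[10](italic(p))),
                  title = attr(object, "predictor")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cluster_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$inertia)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "suggested_k"),
                        linetype = "dashed") +
    ggplot2::labs(x = "k", y = "inertia (within-cluster SS)") +
    ggplot2::theme_minimal()
}

#' PCA scatter plots, one image per PC pair
#'
#' @param coords an `invertype_pca`.
#' @param labels optional `cluster_labels` for coloring.
#' @param pc_pairs list of length-2 PC index vectors.
#' @param dir output directory (created if needed).
#' @param width,height,dpi image geometry.
#' @return character vector of PNG paths written.
#' @export
scatter_plot <- function(coords, labels = NULL,
                         pc_pairs = list(c(1, 2)), dir = ".",
                         width = 6, height = 5, dpi = 150) {
  if (length(coords$sample_ids) == 0L) abort("no samples to plot")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(pc_pairs, function(pair) {
    p <- autoplot.invertype_pca(coords, labels = labels, pcs = pair)
    path <- file.path(dir, sprintf("pca_pc%d_pc%d.png", pair[1], pair[2]))
    ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi,
                    device = "png")
    path
  }, "")
}

#' Manhattan plot of an association track
#'
#' x is position in Mb, y is `-log10(p)` capped at 300 (the track's
#' p-value floor). Tracks above 200,000 SNPs are thinned deterministically:
#' every `ceil(n / 200000)`-th point by position is kept, plus every point
#' with `-log10(p) >= 4`.
#'
#' @param track an `assoc_track`.
#' @param path output PNG path.
#' @param width,height,dpi image geometry.
#' @return `path`, invisibly.
#' @export
manhattan_plot <- function(track, path, width = 8, height = 4, dpi = 150) {
  p <- autoplot.assoc_track(track)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi,
                  device = "png")
  invisible(path)
}
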