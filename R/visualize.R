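# Scatter views of the reduced data: first two principal components, or a
# t-SNE projection of the autoencoder bottleneck (see tsne_embed).

#' First-two-component PCA scatter frame
#'
#' Takes a score matrix from [pca_transform()] (or any embedding with at
#' least two columns) and returns its first two columns as plotting
#' coordinates.
#'
#' @param emb numeric score/embedding matrix with >= 2 columns.
#' @param labels optional per-sample labels (subpopulation or cluster).
#' @return a [plot_frame()].
#' @export
pca_scatter <- function(emb, labels = NULL) {
  emb <- as.matrix(unclass(emb))
  if (ncol(emb) < 2L)
    stop2("need at least two components for a 2-D scatter")
  plot_frame(emb[, 1:2, drop = FALSE], labels = labels, ids = rownames(emb),
             axes = c("PC1", "PC2"))
}

#' Write a scatter plot of a plot frame
#'
#' Colours points by label with a legend (one entry per distinct label).
#'
#' @param frame a [plot_frame()].
#' @param path output file path.
#' @param format `"png"` or `"svg"`.
#' @param width,height device size in inches.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
export_plot <- function(frame, path, format = c("png", "svg"),
                        width = 6, height = 5, main = "") {
  stopifnot(inherits(frame, "plot_frame"))
  format <- match.arg(format)
  switch(format,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         svg = grDevices::svg(path, width = width, height = height))
  on.exit(grDevices::dev.off())
  axes <- attr(frame, "axes") %||% c("dim1", "dim2")
  labs <- frame$label
  if (all(is.na(labs))) labs <- rep("sample", nrow(frame))
  lv <- sort(unique(labs))
  cols <- grDevices::hcl.colors(max(3L, length(lv)), "Dark 2")[seq_along(lv)]
  graphics::plot(frame$dim1, frame$dim2,
                 col = cols[match(labs, lv)], pch = 19,
                 xlab = axes[1L], ylab = axes[2L], main = main)
  graphics::legend("topright", legend = lv, col = cols, pch = 19, bty = "n")
  invisible(path)
}

#' Export plot-frame coordinates as TSV
#'
#' Columns: sample ID, dim1, dim2, label.
#' @param frame a [plot_frame()].
#' @param path output path.
#' @export
write_plot_frame <- function(frame, path) {
  stopifnot(inherits(frame, "plot_frame"))
  data.table::fwrite(as.data.frame(frame), path, sep = "\t", quote = FALSE)
  invisible(path)
}
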