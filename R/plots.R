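#' Scatter plot of a principal component projection
#'
#' Plots two principal components with marker proteins coloured by
#' class, unlabelled proteins in light grey — the standard overview of
#' an organelle map.
#'
#' @param pca a `PcaResult`.
#' @param dataset the `ProfileSet` the projection came from (provides
#'   marker classes).
#' @param dims which two components to plot (default 1:2).
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, the per-point colour vector.
#' @export
plotPca <- function(pca, dataset, dims = c(1, 2), ...) {
  sc <- pca@scores[, dims, drop = FALSE]
  vf <- pca@varianceFraction[dims]
  mc <- featureInfo(dataset)[rownames(sc), "markerClass"]
  classes <- sort(unique(mc[mc != "unknown"]))
  pal <- grDevices::hcl.colors(max(length(classes), 3), "Dark 3")
  col <- rep("grey85", nrow(sc))
  for (i in seq_along(classes)) col[mc == classes[i]] <- pal[i]
  o <- order(mc != "unknown")  # draw markers on top
  graphics::plot(sc[o, 1], sc[o, 2], col = col[o], pch = 16, cex = 0.6,
                 xlab = sprintf("PC%d (%.1f%%)", dims[1], 100 * vf[1]),
                 ylab = sprintf("PC%d (%.1f%%)", dims[2], 100 * vf[2]), ...)
  graphics::legend("topright", legend = classes, col = pal[seq_along(classes)],
                   pch = 16, cex = 0.7, bty = "n")
  invisible(col)
}

#' Heatmap of a normalised QSep matrix
#'
#' @param qres a `QSepResult`.
#' @param ... further arguments passed to [graphics::image()].
#' @export
plotQSep <- function(qres, ...) {
  m <- qsepNormalised(qres)
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, ]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(n), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(m)), las = 2, cex.axis = 0.7)
  invisible(m)
}
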