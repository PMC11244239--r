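# Visual summaries: connectivity heatmaps and thresholded scalp graphs.

#' Heatmap of a connectivity matrix
#'
#' @param m `C x C` PLI or cwPLI matrix.
#' @param main Plot title.
#' @param bounds Colour scale bounds (default `c(0, 1)`).
#' @return Invisibly, `m`.
#' @export
plot_connectivity_heatmap <- function(m, main = "cwPLI", bounds = c(0, 1)) {
  m <- unclass(m)
  C <- nrow(m)
  ch <- attr(m, "channel_names")
  if (is.null(ch)) ch <- paste0("ch", seq_len(C))
  graphics::image(seq_len(C), seq_len(C), t(m[C:1, , drop = FALSE]),
                  col = hcl.colors(256, "Viridis"),
                  zlim = bounds, axes = FALSE, xlab = "", ylab = "",
                  main = main)
  graphics::axis(1, at = seq_len(C), labels = ch, las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(C), labels = rev(ch), las = 2,
                 cex.axis = 0.6)
  invisible(m)
}

#' Thresholded connectivity graph on the scalp layout
#'
#' Draws an edge between electrodes whose connectivity exceeds the
#' threshold (default 0.10), on the 2-D projection of the 10-20 montage.
#' Sparser graphs indicate weaker functional connectivity.
#'
#' @param m `C x C` connectivity matrix over the 19-channel montage.
#' @param threshold Edge threshold (default 0.10).
#' @param main Plot title.
#' @return Invisibly, the number of edges drawn.
#' @export
plot_connectivity_graph <- function(m, threshold = 0.10,
                                    main = "functional connectivity") {
  m <- unclass(m)
  xyz <- montage_coords()
  # azimuthal projection: vertex at origin, nose up
  r2 <- acos(pmin(pmax(xyz[, "z"], -1), 1))
  az <- atan2(xyz[, "y"], xyz[, "x"])
  px <- r2 * cos(az); py <- r2 * sin(az)
  graphics::plot(px, py, asp = 1, pch = 21, bg = "grey80", cex = 2.2,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  n_edges <- 0L
  C <- nrow(m)
  for (i in seq_len(C - 1L))
    for (j in (i + 1L):C)
      if (m[i, j] > threshold) {
        graphics::segments(px[i], py[i], px[j], py[j],
                           col = grDevices::adjustcolor("steelblue", 0.7),
                           lwd = 0.5 + 3 * m[i, j])
        n_edges <- n_edges + 1L
      }
  graphics::points(px, py, pch = 21, bg = "grey80", cex = 2.2)
  graphics::text(px, py, rownames(xyz), cex = 0.5)
  invisible(n_edges)
}
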