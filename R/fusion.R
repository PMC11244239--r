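# Fusion of connectivity and complexity into one channel-by-channel map:
# the cwPLI upper triangle carries pairwise synchrony, the diagonal (which
# carries no PLI information) carries the min-max-rescaled per-channel
# Sample Entropy, and the lower triangle mirrors the upper so the map stays
# symmetric. The map is rendered as an RGB image through a fixed
# blue-to-yellow (viridis) 256-entry colormap.

#' 256-entry blue-to-yellow colormap lookup table
#'
#' @return Integer matrix `[256 x 3]` of RGB values in `[0, 255]`.
#' @export
fusion_colormap <- function() {
  unname(t(col2rgb(hcl.colors(256, "Viridis"))))
}

#' Fuse a cwPLI matrix with a Sample Entropy vector
#'
#' Upper triangle (i < j) = `cwpli[i, j]`; diagonal = Sample Entropy
#' rescaled to `[0, 1]` using the supplied bounds (so both feature families
#' share the colormap range); lower triangle mirrors the upper. The bounds
#' should be computed on training data only and reused for held-out
#' epochs.
#'
#' @param cwpli `C x C` weighted (or plain) PLI matrix.
#' @param saen Numeric vector of length `C`, or `NULL` for a zero diagonal.
#' @param saen_bounds Rescaling bounds: either `c(lo, hi)` applied to all
#'   channels, or a `2 x C` matrix of per-channel `(lo, hi)` rows.
#'   Per-channel bounds remove the between-channel entropy differences
#'   (a subject-identity nuisance) and keep the within-channel class
#'   signal. Defaults to `range(saen)`.
#' @return Symmetric `C x C` fusion matrix in `[0, 1]` (given inputs in
#'   range).
#' @export
fuse <- function(cwpli, saen = NULL, saen_bounds = NULL) {
  cwpli <- unclass(cwpli)
  C <- nrow(cwpli)
  out <- cwpli
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  if (is.null(saen)) {
    diag(out) <- 0
    return(out)
  }
  if (length(saen) != C) stop("channel counts of cwpli and saen differ")
  if (is.null(saen_bounds)) saen_bounds <- range(saen)
  if (is.matrix(saen_bounds)) {
    lo <- saen_bounds[1, ]; hi <- saen_bounds[2, ]
  } else {
    lo <- rep(saen_bounds[1], C); hi <- rep(saen_bounds[2], C)
  }
  span <- hi - lo
  scaled <- ifelse(span > 0, (saen - lo) / pmax(span, .Machine$double.eps),
                   0.5)
  diag(out) <- pmin(pmax(scaled, 0), 1)
  out
}

#' Render a feature matrix as an RGB image
#'
#' Min-max normalises with fixed global bounds (default `[0, 1]`, the cwPLI
#' range), quantises through the 256-entry colormap, and upscales to
#' `size x size` pixels by nearest neighbour.
#'
#' @param m Finite numeric `C x C` matrix.
#' @param size Output image side in pixels (default 32).
#' @param bounds Normalisation bounds (default `c(0, 1)`).
#' @param lut Colormap lookup table (default [fusion_colormap()]).
#' @return Integer array `[size x size x 3]` with values in `[0, 255]`.
#' @export
to_rgb <- function(m, size = 32L, bounds = c(0, 1), lut = fusion_colormap()) {
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite feature value at cell (%d, %d)", bad[1], bad[2]))
  }
  C <- nrow(m)
  v <- (m - bounds[1]) / (bounds[2] - bounds[1])
  v <- pmin(pmax(v, 0), 1)
  idx <- pmin(255L, as.integer(floor(v * 256))) + 1L  # 1..256
  map <- ceiling(seq_len(size) * C / size)            # pixel -> cell
  big_idx <- matrix(idx, C, C)[map, map, drop = FALSE]
  out <- array(0L, dim = c(size, size, 3L))
  for (ch in 1:3) out[, , ch] <- matrix(lut[big_idx, ch], size, size)
  out
}

#' Decode an RGB feature image back to its normalised matrix
#'
#' Inverse of [to_rgb()] up to colormap quantisation: each `C x C` block's
#' colour is matched to the nearest colormap entry.
#'
#' @param img Integer array `[size x size x 3]`.
#' @param C Number of channels of the original matrix.
#' @param lut Colormap lookup table used for encoding.
#' @return `C x C` matrix of normalised values in `[0, 1]`.
#' @export
rgb_to_matrix <- function(img, C, lut = fusion_colormap()) {
  size <- dim(img)[1]
  map <- ceiling(seq_len(size) * C / size)
  out <- matrix(0, C, C)
  for (i in seq_len(C))
    for (j in seq_len(C)) {
      px <- c(mean(img[map == i, map == j, 1]),
              mean(img[map == i, map == j, 2]),
              mean(img[map == i, map == j, 3]))
      d2 <- colSums((t(lut) - px)^2)
      # a handful of adjacent colormap entries quantise to the same 8-bit
      # colour; average over ties so those cells decode to the run centre
      out[i, j] <- (mean(which(d2 == min(d2))) - 0.5) / 256
    }
  out
}
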