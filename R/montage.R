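#' Standard 19-channel 10-20 montage
#'
#' Channel order is frozen package-wide: every matrix produced by the
#' connectivity, complexity and fusion stages indexes channels in this
#' order.
#'
#' @return Character vector of the 19 electrode names.
#' @export
montage_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

#' Cartesian unit-sphere coordinates of the 10-20 montage
#'
#' Idealised electrode positions (x = right ear, y = nasion, z = vertex)
#' used by bad-channel interpolation to weight neighbouring electrodes by
#' scalp distance.
#'
#' @return Numeric matrix [19 x 3] with rownames equal to
#'   [montage_channels()] and columns x, y, z.
#' @export
montage_coords <- function() {
  deg <- pi / 180
  # inclination from the vertex, azimuth from the right-ear axis towards
  # the nasion (positive = left hemisphere); the conventional idealised
  # 10-20 table.
  tab <- rbind(
    Fp1 = c(92, 108), Fp2 = c(92, 72),
    F7  = c(92, 144), F3  = c(60, 129), Fz  = c(46, 90),
    F4  = c(60, 51),  F8  = c(92, 36),
    T3  = c(92, 180), C3  = c(46, 180), Cz  = c(0, 0),
    C4  = c(46, 0),   T4  = c(92, 0),
    T5  = c(92, -144), P3 = c(60, -129), Pz = c(46, -90),
    P4  = c(60, -51), T6  = c(92, -36),
    O1  = c(92, -108), O2 = c(92, -72)
  )
  inc <- tab[, 1] * deg
  az  <- tab[, 2] * deg
  xyz <- cbind(x = sin(inc) * cos(az),
               y = sin(inc) * sin(az),
               z = cos(inc))
  rownames(xyz) <- rownames(tab)
  xyz[montage_channels(), , drop = FALSE]
}

# Fixed per-channel phase lags for the synthetic generator, drawn once per
# montage from a fixed-seed uniform on (0.1, pi - 0.1) so no channel pair is
# exactly zero-lag (PLI discards zero-lag synchrony).
montage_lags <- function(n_channels = 19L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(1020L)
  runif(n_channels, 0.1, pi - 0.1)
}

# run expr with a local RNG state derived from `seed`, restoring the
# caller's stream afterwards; all package randomness funnels through this
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
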