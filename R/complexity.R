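# Sample Entropy: -ln of the ratio of (m+1)- to m-length template-match
# counts under Chebyshev distance, self-matches excluded. Higher values =
# more irregular signal.

#' Sample Entropy of a time series
#'
#' Templates of length `m` are compared under the Chebyshev (maximum
#' coordinate) distance; a pair matches when its distance is strictly below
#' the radius. The radius is `r` times the series' standard deviation by
#' default (`relative_r = TRUE`), which makes the estimate invariant to
#' amplitude scaling, or an absolute radius otherwise.
#'
#' When no template pair matches at length `m + 1` the statistic is
#' undefined (`-ln 0`); the value is then capped at `ln(K - m)` with a
#' warning so downstream feature maps stay finite.
#'
#' @param x Numeric vector, length `K > m + 1`.
#' @param m Template length (default 2).
#' @param r Similarity radius (default 0.2, in units of `sd(x)`).
#' @param relative_r If `TRUE`, radius is `r * sd(x)`.
#' @return Sample entropy in nats (non-negative).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2, relative_r = TRUE) {
  K <- length(x)
  m <- as.integer(m)
  if (m < 1L || r <= 0) stop("need m >= 1 and r > 0")
  if (K <= m + 1L) stop("series too short: need K > m + 1")
  r_abs <- if (relative_r) r * sd(x) else r
  if (r_abs == 0) return(0)  # constant series: every template matches
  cnt <- .sampen_counts(as.numeric(x), m, r_abs)
  A <- cnt[1]; B <- cnt[2]
  if (B == 0 || A == 0) {
    warning("no template matches; Sample Entropy undefined, capped at ln(K - m)")
    return(log(K - m))
  }
  -log(A / B)
}

#' Per-channel Sample Entropy of an epoch set
#'
#' @param ep An [epoch_set()].
#' @param m,r,relative_r Passed to [sample_entropy()].
#' @return Matrix `[C x n_epochs]` of entropies (channel order preserved),
#'   with `channel_names` attribute.
#' @export
saen_vector <- function(ep, m = 2L, r = 0.2, relative_r = TRUE) {
  stopifnot(inherits(ep, "epoch_set"))
  d <- dim(ep$epochs)
  out <- matrix(0, d[1], d[3])
  for (e in seq_len(d[3]))
    for (ch in seq_len(d[1]))
      out[ch, e] <- sample_entropy(ep$epochs[ch, , e], m = m, r = r,
                                   relative_r = relative_r)
  attr(out, "channel_names") <- ep$channel_names
  out
}
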