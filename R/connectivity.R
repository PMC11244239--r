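# Phase Lag Index connectivity and its correlation weighting.
#
# PLI between two channels is |mean_k sign(dphi_k)| where dphi_k is the
# wrapped instantaneous-phase difference at sample k: 0 when there is no
# consistent lag (or only zero-lag synchrony, e.g. volume conduction),
# 1 for perfectly asymmetric phase locking. The correlation weight of a
# channel pair scores, over all stroke x control subject pairs, how
# consistently that pair's subject-level PLI separates the groups; the
# cwPLI matrix is the elementwise product of PLI and weights.

#' Instantaneous phase of a signal
#'
#' Angle of the analytic signal, computed by frequency-domain construction
#' (positive frequencies doubled, negative zeroed).
#'
#' @param x Numeric vector (finite, length >= 8).
#' @return Phase per sample in `(-pi, pi]`. A constant signal has no
#'   defined phase and returns zeros with a warning.
#' @export
instantaneous_phase <- function(x) {
  K <- length(x)
  if (K < 8L) stop("need at least 8 samples")
  if (!all(is.finite(x))) stop("non-finite samples")
  if (max(x) - min(x) < .Machine$double.eps * max(1, abs(x[1]))) {
    warning("constant signal: instantaneous phase is undefined")
    return(rep(0, K))
  }
  X <- fft(x)
  h <- numeric(K)
  if (K %% 2L == 0L) {
    h[1L] <- 1; h[K / 2L + 1L] <- 1; h[2L:(K / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((K + 1L) / 2L)] <- 2
  }
  analytic <- fft(X * h, inverse = TRUE) / K
  Arg(analytic)
}

# wrap angles to (-pi, pi]
.wrap_phase <- function(d) Arg(exp(1i * d))

#' Phase Lag Index of two epochs
#'
#' `|mean_k sign(dphi_k)|` with the phase difference wrapped to
#' `(-pi, pi]`; differences smaller in magnitude than `tol` count as sign
#' zero, so numerically identical channels give PLI 0 rather than
#' noise-driven values.
#'
#' @param x,y Numeric vectors of equal length.
#' @param tol Zero-phase-difference tolerance in radians.
#' @return PLI in `[0, 1]`.
#' @export
pli <- function(x, y, tol = 1e-9) {
  if (length(x) != length(y)) stop("epochs must have equal length")
  d <- .wrap_phase(instantaneous_phase(x) - instantaneous_phase(y))
  s <- sign(d)
  s[abs(d) < tol] <- 0
  abs(mean(s))
}

# PLI for all channel pairs given a phase matrix [C x K]
.pli_from_phase <- function(ph, tol = 1e-9) {
  C <- nrow(ph)
  E <- exp(1i * ph)
  out <- matrix(0, C, C)
  for (i in seq_len(C - 1L)) {
    # Im(E_i * conj(E_j)) = sin(phi_i - phi_j): same sign as the wrapped
    # difference, zero exactly when the difference is 0 (or +-pi)
    si <- E[i, ]
    for (j in (i + 1L):C) {
      d <- Im(si * Conj(E[j, ]))
      s <- sign(d)
      s[abs(d) < tol] <- 0
      out[i, j] <- out[j, i] <- abs(mean(s))
    }
  }
  out
}

#' Per-epoch PLI matrices of an epoch set
#'
#' Computes the Hilbert phase of every channel within each epoch and the
#' PLI of every channel pair. Only the upper triangle is computed and
#' mirrored; the diagonal is zero.
#'
#' @param ep An [epoch_set()] with at least 2 channels.
#' @return Array `[C x C x n_epochs]` with `channel_names` attribute, class
#'   `pli_array`.
#' @export
pli_matrix <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  d <- dim(ep$epochs)
  if (d[1] < 2L) stop("need at least 2 channels")
  out <- array(0, dim = c(d[1], d[1], d[3]))
  for (e in seq_len(d[3])) {
    ph <- t(apply(ep$epochs[, , e, drop = FALSE][, , 1], 1,
                  instantaneous_phase))
    out[, , e] <- .pli_from_phase(ph)
  }
  attr(out, "channel_names") <- ep$channel_names
  class(out) <- "pli_array"
  out
}

#' Subject-level PLI matrix
#'
#' Mean of the per-epoch PLI matrices: the subject summary entering the
#' correlation-weight computation.
#'
#' @param x A `pli_array` from [pli_matrix()] or an [epoch_set()].
#' @return Symmetric `C x C` matrix, zero diagonal.
#' @export
subject_pli <- function(x) {
  if (inherits(x, "epoch_set")) x <- pli_matrix(x)
  m <- apply(unclass(x), c(1, 2), mean)
  attr(m, "channel_names") <- attr(x, "channel_names")
  m
}

#' Group-discrimination correlation weights
#'
#' For each channel pair (i, j), compares the subject-level PLI of every
#' stroke subject against every control subject (P x M ordered cross-group
#' comparisons): `n_l` counts stroke > control, `n_s` counts stroke <
#' control, ties count to neither, and the weight is
#' `|n_l - n_s| / (P * M)`, in `[0, 1]`. A pair whose PLI consistently
#' separates the groups (in either direction) gets weight near 1; an
#' uninformative pair gets weight near 0.
#'
#' @param stroke_plis List of subject-level PLI matrices (stroke group).
#' @param control_plis List of subject-level PLI matrices (control group).
#' @return Symmetric `C x C` weight matrix, class `correlation_weights`,
#'   with attributes `n_stroke` and `n_control`.
#' @export
correlation_weights <- function(stroke_plis, control_plis) {
  P <- length(stroke_plis); M <- length(control_plis)
  if (P < 1L || M < 1L) stop("both groups must be non-empty")
  C <- nrow(stroke_plis[[1]])
  S <- vapply(stroke_plis, identity, matrix(0, C, C))   # [C x C x P]
  Ct <- vapply(control_plis, identity, matrix(0, C, C)) # [C x C x M]
  w <- matrix(0, C, C)
  for (i in seq_len(C - 1L)) {
    for (j in (i + 1L):C) {
      s <- S[i, j, ]; cc <- Ct[i, j, ]
      n_l <- sum(outer(s, cc, ">"))
      n_s <- sum(outer(s, cc, "<"))
      w[i, j] <- w[j, i] <- abs(n_l - n_s) / (P * M)
    }
  }
  attr(w, "n_stroke") <- P
  attr(w, "n_control") <- M
  attr(w, "channel_names") <- attr(stroke_plis[[1]], "channel_names")
  class(w) <- c("correlation_weights", class(w))
  w
}

#' Apply correlation weights to PLI matrices
#'
#' Elementwise product; preserves symmetry and the `[0, 1]` range, and the
#' weighted matrix is bounded above by the unweighted one.
#'
#' @param pli_x A single `C x C` PLI matrix or a `pli_array`.
#' @param w A [correlation_weights()] matrix of matching dimension.
#' @return Object of the same shape as `pli_x`.
#' @export
apply_weights <- function(pli_x, w) {
  wm <- unclass(w)
  if (is.matrix(pli_x)) {
    if (!all(dim(pli_x) == dim(wm))) stop("channel sets do not match")
    return(pli_x * wm)
  }
  x <- unclass(pli_x)
  if (!all(dim(x)[1:2] == dim(wm))) stop("channel sets do not match")
  out <- array(apply(x, 3, function(m) m * wm), dim = dim(x))
  attributes(out) <- attributes(pli_x)
  out
}

#' Mean of the off-diagonal entries of a connectivity matrix
#'
#' @param m Square matrix (or `pli_array`, averaged over epochs first).
#' @return Scalar mean connectivity.
#' @export
mean_connectivity <- function(m) {
  if (inherits(m, "pli_array")) m <- subject_pli(m)
  m <- unclass(m)
  mean(m[row(m) != col(m)])
}
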