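#' Construct a continuous multichannel EEG recording
#'
#' The basic container moved through the pipeline: a channels-by-samples
#' numeric matrix in microvolts together with channel names, sampling rate
#' and the subject's class label (1 = ischemic stroke, 0 = non-stroke
#' control, `NA` = unlabelled).
#'
#' @param data Numeric matrix `[channels x samples]`, microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param subject_id Identifier string.
#' @param label Binary class label (0/1) or `NA`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = rownames(data),
                          subject_id = "subject", label = NA_integer_) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix [channels x samples]")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("one channel name per data row required")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar")
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         subject_id = subject_id, label = label),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s), label=%s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, format(x$label)))
  invisible(x)
}

#' Construct an epoch set
#'
#' Fixed-length, contiguous, non-overlapping windows cut from a recording,
#' stored as a 3-D array `[channels x samples_per_epoch x n_epochs]`.
#'
#' @param epochs 3-D numeric array `[channels x samples x n_epochs]`.
#' @param fs Sampling rate in Hz.
#' @param epoch_length_s Window length in seconds.
#' @param channel_names Channel names (length = dim 1).
#' @param subject_id,label Propagated subject metadata.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs, epoch_length_s, channel_names,
                      subject_id = "subject", label = NA_integer_) {
  stopifnot(is.array(epochs), length(dim(epochs)) == 3L)
  if (dim(epochs)[2] != round(fs * epoch_length_s))
    stop("samples per epoch must equal fs * epoch_length_s")
  structure(
    list(epochs = epochs, fs = fs, epoch_length_s = epoch_length_s,
         channel_names = channel_names, subject_id = subject_id,
         label = label),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %s: %d epochs of %d ch x %d samples (%g s @ %g Hz), label=%s\n",
              x$subject_id, d[3], d[1], d[2], x$epoch_length_s, x$fs,
              format(x$label)))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param ep An `epoch_set`.
#' @return Integer count.
#' @export
n_epochs <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  dim(ep$epochs)[3]
}
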