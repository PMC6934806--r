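#' Epoched multichannel recording
#'
#' Container for an epoched multichannel time series, the basic input of all
#' downstream analyses. Data are stored as a channels x samples x epochs
#' array together with the sampling rate, channel labels and a modality tag.
#'
#' @param data numeric array, channels x samples x epochs. A channels x
#'   samples matrix is accepted and treated as a single epoch.
#' @param fs sampling rate in Hz.
#' @param channel_labels optional character vector of channel names; defaults
#'   to `ch1, ch2, ...`.
#' @param modality one of `"EEG-like"`, `"MEG-like"`, `"synthetic"`.
#' @return an object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, fs,
                              channel_labels = NULL,
                              modality = c("synthetic", "EEG-like", "MEG-like")) {
  modality <- match.arg(modality)
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a channels x samples x epochs array")
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("'fs' must be a positive scalar")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(dim(data)[1L]))
  if (length(channel_labels) != dim(data)[1L])
    stop("length of 'channel_labels' must equal the number of channels")
  structure(list(data = data, fs = fs,
                 channel_labels = channel_labels, modality = modality),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoched recording (%s): %d channels x %d samples x %d epochs @ %g Hz\n",
              x$modality, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' @export
dim.epoched_recording <- function(x) dim(x$data)

#' Average-reference and demean an epoched recording
#'
#' Re-references every sample to the instantaneous channel mean (average
#' reference) and removes the per-epoch, per-channel mean. No resampling or
#' filtering is performed. The operation is idempotent.
#'
#' @param recording an [epoched_recording].
#' @return the preprocessed `epoched_recording`.
#' @export
preprocess <- function(recording) {
  stopifnot(inherits(recording, "epoched_recording"))
  x <- recording$data
  if (dim(x)[1L] < 2L)
    stop("average reference is undefined for a single channel")
  for (e in seq_len(dim(x)[3L])) {
    xe <- x[, , e, drop = FALSE][, , 1L]
    xe <- sweep(xe, 2L, colMeans(xe))      # average reference per sample
    xe <- sweep(xe, 1L, rowMeans(xe))      # per-channel epoch mean
    x[, , e] <- xe
  }
  recording$data <- x
  recording
}
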