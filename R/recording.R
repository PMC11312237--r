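#' Construct an EEG recording object
#'
#' Bundles a channels-by-samples amplitude matrix (microvolts) with its
#' sampling rate, channel labels, subject identifier and class label.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one label per row of `data`.
#' @param subject_id Subject identifier string.
#' @param class_label One of `"MCI"`, `"HC"`, `"unknown"`.
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(300), 3), fs = 100,
#'                      channel_labels = c("Fp1", "Cz", "O2"))
#' rec
eeg_recording <- function(data, fs, channel_labels,
                          subject_id = "S1", class_label = "unknown") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  channel_labels <- as.character(channel_labels)
  if (nrow(data) != length(channel_labels)) {
    stop("number of rows of `data` must equal length(channel_labels)",
         call. = FALSE)
  }
  if (anyNA(data) || !all(is.finite(data))) {
    stop("recording data contains non-finite values", call. = FALSE)
  }
  class_label <- match.arg(class_label, c("MCI", "HC", "unknown"))
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = as.character(subject_id), class_label = class_label),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$class_label, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Construct an EEG segment object
#'
#' A fixed-duration window of a recording; produced by
#' [segment_recording()].
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Channel labels, one per row.
#' @param subject_id Parent subject identifier.
#' @param class_label Class label inherited from the parent recording.
#' @param segment_index 0-based index of the window within the recording.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, fs, channel_labels, subject_id = "S1",
                        class_label = "unknown", segment_index = 0L) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         subject_id = as.character(subject_id),
         class_label = match.arg(class_label, c("MCI", "HC", "unknown")),
         segment_index = as.integer(segment_index)),
    class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s[%d] (%s): %d x %d @ %g Hz\n",
              x$subject_id, x$segment_index, x$class_label,
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}
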