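#' Band-pass filter a recording
#'
#' Applies a Butterworth band-pass (default 0.5-32 Hz, order 5) to every
#' channel independently. The filter is run forward and backward
#' (zero-phase), which doubles the effective order but leaves sub-band
#' waveforms undistorted in phase — important because downstream entropy
#' measures operate on the time course, not just the spectrum.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Pass-band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order Filter order (per direction).
#' @return A filtered [eeg_recording()] of the same shape.
#' @export
bandpass_filter <- function(rec, low_hz = 0.5, high_hz = 32, order = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= rec$fs / 2) {
    stop("high_hz must be below the Nyquist frequency fs/2 = ", rec$fs / 2,
         call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (rec$fs / 2), type = "pass")
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    out$data[i, ] <- signal::filtfilt(bf, rec$data[i, ])
  }
  out
}

#' Partition a recording into fixed-length segments
#'
#' Cuts the recording into non-overlapping, contiguous windows of
#' `seg_len_s` seconds starting at sample 1; a trailing remainder shorter
#' than one window is discarded. Segments never straddle subjects.
#'
#' @param rec An [eeg_recording()].
#' @param seg_len_s Segment length in seconds (default 10).
#' @return List of [eeg_segment()] objects (possibly empty, with a
#'   warning, when the recording is shorter than one segment).
#' @export
#' @examples
#' cfg <- cohort_config(n_hc = 1, n_mci = 0, duration_s = 30, fs = 128)
#' rec <- generate_subject(cfg, "HC", 1)
#' length(segment_recording(rec, seg_len_s = 10))
segment_recording <- function(rec, seg_len_s = 10) {
  stopifnot(inherits(rec, "eeg_recording"), seg_len_s > 0)
  n_seg_samp <- as.integer(round(seg_len_s * rec$fs))
  n_seg <- ncol(rec$data) %/% n_seg_samp
  if (n_seg == 0L) {
    warning("recording shorter than one segment; returning empty list")
    return(list())
  }
  lapply(seq_len(n_seg) - 1L, function(k) {
    eeg_segment(rec$data[, (k * n_seg_samp + 1L):((k + 1L) * n_seg_samp),
                         drop = FALSE],
                fs = rec$fs, channel_labels = rec$channel_labels,
                subject_id = rec$subject_id, class_label = rec$class_label,
                segment_index = k)
  })
}
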