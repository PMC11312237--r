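#' Parameters of the non-linear signal measures
#'
#' @param threshold_alpha Amplitude threshold of the threshold entropy,
#'   in the signal's units after scaling; must lie in (0, 1). Default 0.2.
#' @param norm_power_p Exponent of the norm entropy, >= 1. Default 1.1.
#' @param sure_threshold Amplitude threshold of the SURE entropy, > 2.
#'   Default 3.
#' @param log_eps Zero-guard added inside logarithm terms of the
#'   log-energy and transformation-Shannon measures, which are otherwise
#'   undefined at zero samples. Default 1e-12.
#' @return An object of class `measure_params`.
#' @export
measure_params <- function(threshold_alpha = 0.2, norm_power_p = 1.1,
                           sure_threshold = 3, log_eps = 1e-12) {
  if (!(threshold_alpha > 0 && threshold_alpha < 1)) {
    stop("`threshold_alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (norm_power_p < 1) stop("`norm_power_p` must be >= 1", call. = FALSE)
  if (sure_threshold <= 2) stop("`sure_threshold` must be > 2", call. = FALSE)
  structure(list(threshold_alpha = threshold_alpha, norm_power_p = norm_power_p,
                 sure_threshold = sure_threshold, log_eps = log_eps),
            class = "measure_params")
}

#' Names of the available measures
#' @return Character vector of the seven measure codes.
#' @export
measure_names <- function() {
  c("Eng", "BP", "ThEn", "NoEn", "SuEn", "LogEn", "TShEn")
}

#' Compute a non-linear scalar measure of a signal
#'
#' The seven measures summarise a (sub-band) signal `s` of `N` samples:
#' \describe{
#'   \item{Eng}{energy, `sum(s^2)`}
#'   \item{BP}{log band power, `log(mean(s^2))` (natural log)}
#'   \item{ThEn}{threshold entropy: the number of time instants whose
#'     amplitude exceeds the threshold, `#\{i : |s_i| > alpha\}`}
#'   \item{NoEn}{norm entropy, `sum(|s_i|^p)`}
#'   \item{SuEn}{SURE entropy,
#'     `N - #\{i : |s_i| <= t\} + sum(min(s_i^2, t^2))`}
#'   \item{LogEn}{log-energy entropy, `sum(log(s_i^2 + eps))`}
#'   \item{TShEn}{transformation-Shannon entropy,
#'     `mean((s_i^2 + eps) * log(s_i^2 + eps))` (as defined, without a
#'     leading minus sign, so it is the negative of the conventional
#'     Shannon form up to scale)}
#' }
#' Amplitude thresholds are compared against `|s_i|`: the signals are
#' zero-mean after high-pass filtering, so a signed comparison would
#' discard half of the excursions. `eps` is the `log_eps` zero-guard of
#' [measure_params()].
#'
#' @param signal Non-empty numeric vector.
#' @param measure One of `r paste(measure_names(), collapse = ", ")`.
#' @param params A [measure_params()].
#' @return A single numeric value.
#' @export
#' @examples
#' compute_measure(c(1, 2), "Eng")            # 5
#' compute_measure(c(0.1, 0.3, -0.5, 0.05), "ThEn")  # 2
compute_measure <- function(signal, measure = measure_names(),
                            params = measure_params()) {
  measure <- match.arg(measure)
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n == 0L) stop("`signal` must be non-empty", call. = FALSE)
  eps <- params$log_eps
  switch(measure,
    Eng = sum(signal^2),
    BP = {
      mp <- mean(signal^2)
      log(max(mp, eps))               # all-zero signal would give -Inf
    },
    ThEn = sum(abs(signal) > params$threshold_alpha),
    NoEn = sum(abs(signal)^params$norm_power_p),
    SuEn = {
      t2 <- params$sure_threshold^2
      n - sum(abs(signal) <= params$sure_threshold) + sum(pmin(signal^2, t2))
    },
    LogEn = sum(log(signal^2 + eps)),
    TShEn = mean((signal^2 + eps) * log(signal^2 + eps)))
}

# sub-band sources, in the fixed per-channel feature order
feature_sources <- function(level = 4L) {
  c(paste0("cA", level), paste0("cD", level:1), "original")
}

#' Extract the wavelet-feature vector of one segment
#'
#' Each channel contributes six values: the chosen measure applied to the
#' five reconstructed sub-band signals (in the order cA4, cD4, cD3, cD2,
#' cD1) and to the original channel signal. Channels are concatenated in
#' the segment's channel order, giving a vector of length `6 * ch`.
#'
#' @param seg An [eeg_segment()].
#' @param measure Measure code, see [compute_measure()].
#' @param params A [measure_params()].
#' @param wavelet,level Wavelet decomposition settings.
#' @return Numeric vector of length `6 * ch`, named
#'   `<channel>.<source>`.
#' @export
extract_segment_features <- function(seg, measure = "ThEn",
                                     params = measure_params(),
                                     wavelet = "db4", level = 4L) {
  stopifnot(inherits(seg, "eeg_segment"))
  measure <- match.arg(measure, measure_names())
  srcs <- feature_sources(level)
  out <- numeric(nrow(seg$data) * (level + 2L))
  pos <- 0L
  for (i in seq_len(nrow(seg$data))) {
    x <- seg$data[i, ]
    sb <- dwt_subband_signals(x, wavelet = wavelet, level = level)
    for (s in sb) {
      pos <- pos + 1L
      out[pos] <- compute_measure(s, measure, params)
    }
    pos <- pos + 1L
    out[pos] <- compute_measure(x, measure, params)
  }
  names(out) <- paste(rep(seg$channel_labels, each = length(srcs)), srcs,
                      sep = ".")
  out
}

#' Build a feature matrix from a list of segments
#'
#' Row `i` holds the feature vector of `segments[[i]]`; per-column
#' provenance (channel, sub-band source, measure) and per-row class
#' labels are carried along.
#'
#' @param segments List of [eeg_segment()] objects sharing channel
#'   order, channel count and sampling rate.
#' @inheritParams extract_segment_features
#' @return An object of class `feature_matrix` with elements `values`
#'   (numeric matrix, segments x features), `column_meta` (data.frame
#'   with columns channel, source, measure), `labels` (character),
#'   `subject_ids`, `channel_labels`.
#' @export
build_feature_matrix <- function(segments, measure = "ThEn",
                                 params = measure_params(),
                                 wavelet = "db4", level = 4L) {
  measure <- match.arg(measure, measure_names())
  if (length(segments) == 0L) {
    return(new_feature_matrix(matrix(numeric(0), nrow = 0L, ncol = 0L),
                              character(0), character(0), character(0),
                              measure, level))
  }
  ch0 <- segments[[1L]]$channel_labels
  for (s in segments) {
    if (!inherits(s, "eeg_segment") || !identical(s$channel_labels, ch0) ||
        !identical(dim(s$data), dim(segments[[1L]]$data))) {
      stop("all segments must share channel order and shape", call. = FALSE)
    }
  }
  values <- t(vapply(segments, extract_segment_features,
                     numeric(length(ch0) * (level + 2L)),
                     measure = measure, params = params,
                     wavelet = wavelet, level = level))
  dimnames(values) <- NULL                # provenance lives in column_meta
  new_feature_matrix(values,
                     labels = vapply(segments, `[[`, "", "class_label"),
                     subject_ids = vapply(segments, `[[`, "", "subject_id"),
                     channel_labels = ch0, measure = measure, level = level)
}

new_feature_matrix <- function(values, labels, subject_ids, channel_labels,
                               measure, level = 4L) {
  srcs <- feature_sources(level)
  column_meta <- data.frame(
    channel = rep(channel_labels, each = length(srcs)),
    source = rep(srcs, times = length(channel_labels)),
    measure = rep(measure, length.out = length(channel_labels) * length(srcs)),
    stringsAsFactors = FALSE)
  if (ncol(values) > 0L && ncol(values) != nrow(column_meta)) {
    stop("feature count does not match 6 x channels", call. = FALSE)
  }
  structure(list(values = values, column_meta = column_meta,
                 labels = labels, subject_ids = subject_ids,
                 channel_labels = channel_labels, measure = measure),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features (%s; %d channels; %d MCI / %d HC)\n",
              nrow(x$values), ncol(x$values), x$measure,
              length(x$channel_labels), sum(x$labels == "MCI"),
              sum(x$labels == "HC")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Write / read a feature matrix as annotated CSV
#'
#' The file starts with three `#`-prefixed metadata rows (channel,
#' source, measure per column), followed by a regular CSV whose first
#' two columns are the class label and subject id.
#'
#' @param fm A `feature_matrix`.
#' @param path File path.
#' @return `path` (writer) or a `feature_matrix` (reader).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste0("#channel,", paste(fm$column_meta$channel, collapse = ",")), con)
  writeLines(paste0("#source,", paste(fm$column_meta$source, collapse = ",")), con)
  writeLines(paste0("#measure,", paste(fm$column_meta$measure, collapse = ",")), con)
  writeLines(paste(c("label", "subject_id",
                     paste0("f", seq_len(ncol(fm$values)))), collapse = ","), con)
  if (nrow(fm$values) > 0L) {
    body <- apply(format(fm$values, digits = 17, trim = TRUE, scientific = TRUE),
                  1L, paste, collapse = ",")
    writeLines(paste(fm$labels, fm$subject_ids, body, sep = ","), con)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  hdr <- readLines(path, n = 3L)
  meta <- lapply(hdr, function(l) strsplit(sub("^#[a-z]+,", "", l), ",")[[1L]])
  df <- read.csv(path, skip = 3L, check.names = FALSE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(values) <- NULL
  fm <- new_feature_matrix(values, labels = df$label,
                           subject_ids = df$subject_id,
                           channel_labels = unique(meta[[1L]]),
                           measure = meta[[3L]][1L],
                           level = length(unique(meta[[2L]])) - 2L)
  fm$column_meta <- data.frame(channel = meta[[1L]], source = meta[[2L]],
                               measure = meta[[3L]], stringsAsFactors = FALSE)
  fm
}
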