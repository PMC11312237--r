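#' Read an EEG recording from disk
#'
#' Supports 16-bit EDF (European Data Format) and plain delimited text
#' (comma-separated, one sample per row, header row of channel labels).
#' Amplitudes are returned unchanged apart from the EDF physical-unit
#' conversion inherent to the format.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"edf"` or `"delimited"`.
#' @param subject_id Optional subject id; defaults to the file's metadata
#'   (EDF) or the file name without extension (delimited).
#' @param class_label Optional class label override.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited"),
                           subject_id = NULL, class_label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  rec <- if (format == "edf") read_edf(path) else read_delimited(path)
  if (!is.null(subject_id)) rec$subject_id <- as.character(subject_id)
  if (!is.null(class_label)) {
    rec$class_label <- match.arg(class_label, c("MCI", "HC", "unknown"))
  }
  rec
}

#' Write an EEG recording to disk
#'
#' @param rec An [eeg_recording()].
#' @param path Output file.
#' @param format `"auto"` (by extension), `"edf"` or `"delimited"`.
#'   EDF stores samples as 16-bit integers scaled to each channel's
#'   physical range, so amplitudes round-trip to within the quantisation
#'   step; delimited text preserves full double precision.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "delimited")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  if (format == "edf") write_edf(rec, path) else write_delimited(rec, path)
  invisible(path)
}

read_delimited <- function(path, default_fs = 256) {
  # optional "# fs=<Hz>" comment written by write_recording(); a bare file
  # with just the channel-label header falls back to `default_fs`
  first <- readLines(path, n = 1L)
  fs <- default_fs
  if (grepl("^#", first)) {
    m <- regmatches(first, regexpr("fs=[0-9.]+", first))
    if (length(m) == 1L) fs <- as.numeric(sub("fs=", "", m))
  }
  df <- tryCatch(read.csv(path, check.names = FALSE, comment.char = "#"),
                 error = function(e) stop("cannot parse delimited file ", path,
                                          ": ", conditionMessage(e), call. = FALSE))
  if (ncol(df) < 1L || nrow(df) < 1L) {
    stop("delimited recording has no channels or no samples", call. = FALSE)
  }
  data <- t(as.matrix(df))
  if (anyNA(data) || !is.numeric(data)) {
    stop("delimited recording contains missing or non-numeric values", call. = FALSE)
  }
  eeg_recording(data, fs = fs, channel_labels = names(df),
                subject_id = sub("\\.[^.]*$", "", basename(path)))
}

write_delimited <- function(rec, path) {
  ok <- tryCatch({
    con <- file(path, "w")
    writeLines(sprintf("# fs=%.10g", rec$fs), con)
    writeLines(paste(rec$channel_labels, collapse = ","), con)
    m <- format(t(rec$data), digits = 17, trim = TRUE, scientific = TRUE)
    writeLines(apply(m, 1L, paste, collapse = ","), con)
    close(con)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write ", path, call. = FALSE)
  invisible(path)
}

# --- EDF (16-bit, physical units uV) ------------------------------------
# Minimal EDF implementation: one data record per second, all channels at
# the recording's sampling rate. The class label is stashed as a
# "class=<label>" token in the 80-byte recording-id header field because
# EDF has no dedicated field for it.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)", call. = FALSE)
  if (n_rec * fs != ncol(rec$data)) {
    warning("EDF writer truncating ", ncol(rec$data) - n_rec * fs,
            " trailing samples (non-integer number of seconds)")
  }
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(x, 1L, min); pmax_ <- apply(x, 1L, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open ", path, " for writing", call. = FALSE))
  on.exit(close(con), add = TRUE)
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)

  wr(pad_field("0", 8))
  wr(pad_field(rec$subject_id, 80))
  wr(pad_field(paste0("Startdate 01-JAN-2000 class=", rec$class_label), 80))
  wr(pad_field("01.01.00", 8)); wr(pad_field("00.00.00", 8))
  wr(pad_field(256L * (ns + 1L), 8))
  wr(pad_field("", 44))
  wr(pad_field(n_rec, 8)); wr(pad_field("1", 8)); wr(pad_field(ns, 4))

  num_field <- function(v, width) pad_field(formatC(v, format = "g", digits = 7), width)
  wr(paste0(vapply(rec$channel_labels, pad_field, "", width = 16), collapse = ""))
  wr(strrep(" ", 80L * ns))                    # transducer
  wr(paste0(rep(pad_field("uV", 8), ns), collapse = ""))
  wr(paste0(num_field(pmin_, 8), collapse = ""))
  wr(paste0(num_field(pmax_, 8), collapse = ""))
  wr(paste0(rep(pad_field(dmin, 8), ns), collapse = ""))
  wr(paste0(rep(pad_field(dmax, 8), ns), collapse = ""))
  wr(strrep(" ", 80L * ns))                    # prefiltering
  wr(paste0(rep(pad_field(fs, 8), ns), collapse = ""))
  wr(strrep(" ", 32L * ns))

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  dig <- round((x - pmin_) * scale + dmin)     # row-wise recycling of pmin_/scale
  dig <- pmin(pmax(dig, dmin), dmax)
  # records: for each second, channel blocks of fs int16 samples
  idx <- matrix(seq_len(n_rec * fs), nrow = fs)  # column r = samples of record r
  out <- integer(n_rec * ns * fs)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    block <- t(dig[, idx[, r], drop = FALSE])    # fs x ns
    out[pos + seq_len(ns * fs)] <- as.integer(block)
    pos <- pos + ns * fs
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)
  subject_id <- trimws(rd(80))
  rec_id <- trimws(rd(80))
  rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(ns) || ns < 1L) stop("EDF file reports no signals", call. = FALSE)
  fields <- function(width) vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  labels <- fields(16); fields(80); fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1L) {
    stop("EDF reader supports a single sampling rate across signals", call. = FALSE)
  }
  fs <- spr[1L] / dur

  dig <- readBin(con, "integer", n = n_rec * ns * spr[1L], size = 2L,
                 endian = "little")
  if (length(dig) != n_rec * ns * spr[1L]) stop("EDF data truncated", call. = FALSE)
  # layout: record-major, channel blocks of spr samples
  arr <- array(dig, dim = c(spr[1L], ns, n_rec))
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  for (i in seq_len(ns)) data[i, ] <- as.vector(arr[, i, ])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  data <- (data - dmin) * scale + pmin_

  cls <- "unknown"
  m <- regmatches(rec_id, regexpr("class=[A-Za-z]+", rec_id))
  if (length(m) == 1L) {
    cand <- sub("class=", "", m)
    if (cand %in% c("MCI", "HC")) cls <- cand
  }
  eeg_recording(data, fs = fs, channel_labels = labels,
                subject_id = if (nzchar(subject_id)) subject_id else "S1",
                class_label = cls)
}
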