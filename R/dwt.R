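# Discrete wavelet transform with symmetric-extension boundary handling
# and per-band reconstruction. The filter-bank kernels live in compiled
# code (src/dwt_kernels.cpp); coefficient lengths per level follow the
# usual symmetric-padding convention, floor((n + L - 1) / 2) for an
# L-tap filter.

wavelet_filters <- function(wavelet = c("db4", "haar")) {
  wavelet <- match.arg(wavelet)
  # scaling (low-pass synthesis) filters; db4 = Daubechies 8-tap
  h <- switch(wavelet,
    db4 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
            -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728),
    haar = c(1, 1) / sqrt(2))
  L <- length(h)
  dec_hi <- h * rep_len(c(-1, 1), L)   # quadrature mirror of the scaling filter
  list(rec_lo = h, dec_lo = rev(h), dec_hi = dec_hi, rec_hi = rev(dec_hi),
       length = L)
}

#' Decompose a signal into reconstructed wavelet sub-band signals
#'
#' Performs a `level`-deep discrete wavelet decomposition (default db4,
#' level 4) and reconstructs one full-length time-domain signal per
#' coefficient set — the approximation `cA4` and details `cD4 ... cD1` —
#' by zeroing all other coefficients before the inverse transform.
#' By linearity the five signals sum back to the input (perfect
#' reconstruction), which is the invariant the tests rely on. At a
#' 256 Hz sampling rate the level-4 dyadic bands are approximately
#' cA4 0-8 Hz, cD4 8-16, cD3 16-32, cD2 32-64 and cD1 64-128 Hz; note
#' these dyadic edges are close to, but not identical with, the named
#' EEG rhythm bands.
#'
#' @param signal Numeric vector (length >= 2^level).
#' @param wavelet `"db4"` (default) or `"haar"`.
#' @param level Decomposition depth (default 4).
#' @return Named list of numeric vectors `cA4, cD4, cD3, cD2, cD1`
#'   (names follow `level`), each the same length as the input.
#' @export
#' @examples
#' x <- sin(2 * pi * 2 * (0:255) / 256)
#' sb <- dwt_subband_signals(x)
#' max(abs(Reduce(`+`, sb) - x))  # perfect reconstruction, ~1e-15
dwt_subband_signals <- function(signal, wavelet = "db4", level = 4L) {
  signal <- as.numeric(signal)
  level <- as.integer(level)
  if (level < 1L) stop("`level` must be >= 1", call. = FALSE)
  if (length(signal) < 2^level) {
    stop("signal too short for a level-", level, " decomposition", call. = FALSE)
  }
  f <- wavelet_filters(wavelet)
  m <- dwt_subbands_cpp(signal, f$dec_lo, f$dec_hi, f$rec_lo, f$rec_hi, level)
  out <- lapply(seq_len(level + 1L), function(k) m[k, ])
  names(out) <- c(paste0("cA", level), paste0("cD", level:1))
  out
}
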