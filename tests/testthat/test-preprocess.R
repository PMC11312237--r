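make_tone <- function(freq, fs = 256, dur = 4) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sin(2 * pi * freq * t)
}

rms <- function(x) sqrt(mean(x^2))

test_that("band-pass suppresses line noise and DC but passes mid-band", {
  fs <- 256
  rec50 <- eeg_recording(matrix(make_tone(50, fs), 1), fs, "Cz")
  out50 <- bandpass_filter(rec50)
  expect_lt(rms(out50$data[1, ]) / rms(rec50$data[1, ]), 0.05)

  rec10 <- eeg_recording(matrix(make_tone(10, fs), 1), fs, "Cz")
  out10 <- bandpass_filter(rec10)
  expect_lt(abs(rms(out10$data[1, ]) / rms(rec10$data[1, ]) - 1), 0.05)

  # DC rejection is asymptotic: judge the steady state away from the
  # ~2 s edge transients of the 0.5 Hz high-pass
  recdc <- eeg_recording(matrix(rep(7, fs * 30), 1), fs, "Cz")
  outdc <- bandpass_filter(recdc)
  mid <- outdc$data[1, (10 * fs):(20 * fs)]
  expect_lt(rms(mid), 0.05)
})

test_that("filtering is linear and channel-independent", {
  set.seed(2)
  fs <- 128
  x <- rnorm(fs * 3); y <- rnorm(fs * 3)
  as_rec <- function(v) eeg_recording(matrix(v, 1), fs, "Cz")
  f <- function(v) bandpass_filter(as_rec(v))$data[1, ]
  lhs <- f(2 * x - 3 * y)
  rhs <- 2 * f(x) - 3 * f(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-8)

  # two channels filter exactly as each would alone
  rec2 <- eeg_recording(rbind(x, y), fs, c("C3", "C4"))
  out2 <- bandpass_filter(rec2)
  expect_equal(out2$data[1, ], f(x))
  expect_equal(out2$data[2, ], f(y))
})

test_that("cutoffs at or above Nyquist are rejected", {
  rec <- eeg_recording(matrix(rnorm(256), 1), 64, "Cz")
  expect_error(bandpass_filter(rec, 0.5, 32), "Nyquist")
  expect_error(bandpass_filter(rec, 10, 5), "low_hz")
})

test_that("segmentation slices contiguously from sample one and drops the tail", {
  fs <- 128
  rec <- eeg_recording(matrix(rnorm(2 * 25 * fs), 2), fs, c("C3", "C4"),
                       subject_id = "S3", class_label = "MCI")
  segs <- segment_recording(rec, 10)
  expect_length(segs, 2L)
  expect_equal(segs[[1]]$segment_index, 0L)
  expect_identical(segs[[1]]$data, rec$data[, 1:(10 * fs)])
  expect_identical(segs[[2]]$data, rec$data[, (10 * fs + 1):(20 * fs)])
  expect_equal(segs[[2]]$class_label, "MCI")
  # concatenating all segments reproduces the leading portion exactly
  expect_identical(do.call(cbind, lapply(segs, `[[`, "data")),
                   rec$data[, 1:(20 * fs)])
})

test_that("a recording shorter than one segment warns and returns nothing", {
  rec <- eeg_recording(matrix(rnorm(2 * 64), 2), 64, c("C3", "C4"))
  expect_warning(segs <- segment_recording(rec, 10), "shorter")
  expect_length(segs, 0L)
})
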