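test_that("worked examples of the measures are reproduced", {
  expect_equal(compute_measure(c(1, 2), "Eng"), 5)
  expect_equal(compute_measure(c(0.1, 0.3, -0.5, 0.05), "ThEn"), 2)
  expect_equal(compute_measure(c(1, 1, 1), "LogEn"), 0, tolerance = 1e-10)
  # term-by-term: N - #{|s| <= 3} + sum(min(s^2, 9)) = 2 - 1 + 9.25
  expect_equal(compute_measure(c(0.5, 4.0), "SuEn"), 10.25)
  expect_equal(compute_measure(2, "NoEn"), 2^1.1)
})

test_that("all seven measures match a direct-summation oracle", {
  set.seed(42)
  params <- measure_params()
  for (i in 1:100) {
    n <- sample(8:64, 1)
    x <- rnorm(n, sd = sample(c(0.1, 1, 5), 1))
    for (m in measure_names()) {
      got <- compute_measure(x, m, params)
      want <- oracle_measure(x, m)
      expect_equal(got, want, tolerance = 1e-10,
                   label = sprintf("%s on signal %d", m, i))
    }
  }
})

test_that("measure bounds and monotonicity hold", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(50)
    th <- compute_measure(x, "ThEn")
    expect_true(th == round(th) && th >= 0 && th <= length(x))
    expect_gte(compute_measure(x, "Eng"), 0)
    expect_gte(compute_measure(x, "NoEn"), 0)
    # ThEn is non-increasing in the threshold
    alphas <- c(0.05, 0.2, 0.5, 0.9)
    counts <- vapply(alphas, function(a)
      compute_measure(x, "ThEn", measure_params(threshold_alpha = a)), 0)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("degenerate inputs are guarded", {
  expect_error(compute_measure(numeric(0), "Eng"), "non-empty")
  expect_equal(compute_measure(numeric(5), "BP"), log(1e-12))
  expect_true(is.finite(compute_measure(numeric(5), "LogEn")))
  expect_error(measure_params(threshold_alpha = 1.2), "0, 1")
  expect_error(measure_params(norm_power_p = 0.5), ">= 1")
  expect_error(measure_params(sure_threshold = 2), "> 2")
})

test_that("per-channel feature blocks are ordered and channel-local", {
  set.seed(5)
  fs <- 256
  seg <- eeg_segment(matrix(rnorm(19 * 2560), 19), fs, eeg_1020_labels(),
                     class_label = "MCI")
  v <- extract_segment_features(seg, "ThEn")
  expect_length(v, 114L)
  expect_equal(names(v)[1:6],
               paste("Fp1", c("cA4", "cD4", "cD3", "cD2", "cD1", "original"),
                     sep = "."))

  seg1 <- eeg_segment(matrix(rnorm(2560), 1), fs, "Cz")
  expect_length(extract_segment_features(seg1, "Eng"), 6L)

  zero <- eeg_segment(matrix(0, 2, 256), fs, c("C3", "C4"))
  expect_true(all(extract_segment_features(zero, "Eng") == 0))

  # altering channel j only changes that channel's 6 columns
  seg2 <- seg
  seg2$data[4, ] <- seg2$data[4, ] * 3
  v2 <- extract_segment_features(seg2, "ThEn")
  changed <- which(v != v2)
  expect_true(all(changed %in% 19:24))
})

test_that("feature matrices map segments to rows and survive CSV round-trips", {
  set.seed(6)
  segs <- lapply(0:3, function(k)
    eeg_segment(matrix(rnorm(2 * 256), 2), 256, c("C3", "C4"),
                subject_id = paste0("S", k %/% 2),
                class_label = c("HC", "MCI")[k %% 2 + 1], segment_index = k))
  fm <- build_feature_matrix(segs, "SuEn")
  expect_equal(dim(fm$values), c(4L, 12L))
  expect_equal(fm$labels, c("HC", "MCI", "HC", "MCI"))
  expect_equal(fm$column_meta$channel, rep(c("C3", "C4"), each = 6))
  expect_equal(fm$values[2, ], unname(extract_segment_features(segs[[2]], "SuEn")))

  # permuting segments permutes rows identically
  perm <- c(3L, 1L, 4L, 2L)
  fmp <- build_feature_matrix(segs[perm], "SuEn")
  expect_equal(fmp$values, fm$values[perm, ])
  expect_equal(fmp$labels, fm$labels[perm])

  # heterogeneous shapes are refused
  bad <- c(segs, list(eeg_segment(matrix(rnorm(3 * 256), 3), 256,
                                  c("C3", "C4", "Cz"))))
  expect_error(build_feature_matrix(bad, "SuEn"), "share")

  # empty input keeps the structure
  fm0 <- build_feature_matrix(list(), "SuEn")
  expect_equal(nrow(fm0$values), 0L)

  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_equal(back$labels, fm$labels)
  expect_equal(back$column_meta, fm$column_meta)
  expect_equal(back$measure, "SuEn")
})
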