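test_that("evaluation counts follow C(C+1)/2 for both greedy directions", {
  for (C in c(2L, 5L, 12L, 19L)) {
    labels <- paste0("ch", seq_len(C))
    be <- backward_eliminate(NULL, evaluator = mock_evaluator(labels))
    fa <- forward_add(NULL, evaluator = mock_evaluator(labels))
    expect_equal(be$evaluations_performed, C * (C + 1L) / 2L)
    expect_equal(fa$evaluations_performed, C * (C + 1L) / 2L)
    expect_length(be$iterations, C)
    expect_length(fa$iterations, C)
  }
})

test_that("greedy traces are nested and reach the expected extremes", {
  labels <- paste0("ch", 1:6)
  score <- function(ch) sum(match(ch, labels))   # deterministic, asymmetric
  be <- backward_eliminate(NULL, evaluator = mock_evaluator(labels, score))
  sizes_be <- vapply(be$iterations, function(i) length(i$channels), 0L)
  expect_equal(sizes_be, 6:1)
  for (k in 2:6) {
    expect_true(all(be$iterations[[k]]$channels %in%
                    be$iterations[[k - 1]]$channels))
  }
  fa <- forward_add(NULL, evaluator = mock_evaluator(labels, score))
  sizes_fa <- vapply(fa$iterations, function(i) length(i$channels), 0L)
  expect_equal(sizes_fa, 1:6)
  for (k in 2:6) {
    expect_true(all(fa$iterations[[k - 1]]$channels %in%
                    fa$iterations[[k]]$channels))
  }
  # with this additive score the best single channel is the last label
  expect_equal(fa$iterations[[1]]$channels, "ch6")
})

test_that("one informative channel out of three is found by both searches", {
  fm <- toy_fm(n = 80, channels = c("A", "B", "C"), informative = "B",
               shift = 4, seed = 3)
  spec <- classifier_spec("knn", 3)
  cv <- cv_config(5, 11)
  evaluator <- eegselect:::make_cv_evaluator(fm, spec, cv)
  # oracle: exhaustive evaluation of all 7 non-empty subsets
  subsets <- unlist(lapply(1:3, function(k)
    combn(c("A", "B", "C"), k, simplify = FALSE)), recursive = FALSE)
  accs <- vapply(subsets, evaluator, 0)
  singles <- vapply(subsets, length, 0L) == 1L
  best_single <- subsets[singles][[which.max(accs[singles])]]
  expect_equal(best_single, "B")

  be <- backward_eliminate(fm, spec, cv)
  expect_equal(be$iterations[[3]]$channels, "B")
  fa <- forward_add(fm, spec, cv)
  expect_equal(fa$iterations[[1]]$channels, "B")
})

test_that("single-channel ranking drives the incremental baseline", {
  fm <- toy_fm(n = 60, channels = c("A", "B", "C", "D"), informative = "C",
               shift = 4, seed = 9)
  spec <- classifier_spec("knn", 3)
  cv <- cv_config(5, 2)
  rk <- single_channel_ranking(fm, spec, cv)
  expect_equal(nrow(rk), 4L)
  expect_equal(rk$channel[1], "C")
  expect_true(all(diff(rk$accuracy) <= 0))

  inc <- incremental_subsets(rk, fm, spec, cv)
  expect_length(inc$iterations, 4L)
  # the full subset equals the full-channel evaluation with the same folds
  full <- crossval_evaluate(fm, NULL, spec, cv)$accuracy
  expect_equal(inc$iterations[[4]]$accuracy, full)
  # iteration-1 winner of forward addition is the ranking's argmax
  fa <- forward_add(fm, spec, cv)
  expect_equal(fa$iterations[[1]]$channels, rk$channel[1])
})

test_that("traces are reproducible with a deterministic evaluator", {
  fm <- toy_fm(n = 40, seed = 5)
  spec <- classifier_spec("knn", 1)
  cv <- cv_config(5, 6)
  t1 <- backward_eliminate(fm, spec, cv)
  t2 <- backward_eliminate(fm, spec, cv)
  expect_identical(t1$iterations, t2$iterations)
})
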