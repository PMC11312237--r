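test_that("non-dominated sorting matches a brute-force oracle", {
  # worked example: (95,5) dominates the other two
  fr <- fast_nondominated_sort(rbind(c(90, 5), c(95, 5), c(95, 9)))
  expect_equal(fr[[1]], 2L)
  expect_equal(sort(fr[[2]]), c(1L, 3L))

  expect_equal(fast_nondominated_sort(cbind(80, 3)), list(1L))
  same <- matrix(rep(c(90, 4), each = 5), 5)
  expect_equal(fast_nondominated_sort(same), list(1:5))

  set.seed(17)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    objs <- cbind(sample(seq(50, 100, by = 2.5), n, replace = TRUE),
                  sample(1:19, n, replace = TRUE))
    got <- lapply(fast_nondominated_sort(objs), sort)
    expect_equal(got, oracle_fronts(objs), label = paste("instance", i))
  }
})

test_that("crowding distance follows the cuboid definition", {
  expect_equal(crowding_distance(rbind(c(90, 2), c(95, 7))), c(Inf, Inf))
  # evenly spaced collinear points: middle one gets 1 per objective
  cd <- crowding_distance(rbind(c(80, 2), c(90, 5), c(100, 8)))
  expect_equal(cd, c(Inf, 2, Inf))
  # a flat objective contributes nothing
  cd2 <- crowding_distance(rbind(c(80, 4), c(90, 4), c(100, 4)))
  expect_equal(cd2, c(Inf, 1, Inf))
  expect_length(crowding_distance(matrix(numeric(0), 0, 2)), 0L)
})

test_that("reference points tile the simplex", {
  pts <- reference_points(2, 4)
  expect_equal(nrow(pts), 5L)
  expect_true(all(abs(rowSums(pts) - 1) < 1e-12))
  expect_equal(pts[, 1], c(0, 0.25, 0.5, 0.75, 1))
  pts3 <- reference_points(3, 3)
  expect_equal(nrow(pts3), choose(3 + 3 - 1, 3))  # 10 lattice points
  expect_true(all(abs(rowSums(pts3) - 1) < 1e-12))
})

test_that("solutions enforce the at-least-one-channel constraint", {
  expect_error(moo_solution(rep(0, 19), 1), "no_ch")
  s <- moo_solution(c(1, 0, 1, 0), 2)
  expect_equal(s$no_ch, 2L)
  expect_error(moo_solution(c(1, 2, 0), 1), "0/1")
})

test_that("evaluate_solution matches full-channel CV and caches by genotype", {
  fm <- toy_fm(n = 40, seed = 21)
  cv <- cv_config(5, 9)
  sol <- moo_solution(rep(1L, 3), 3)
  cache <- new.env(parent = emptyenv())
  got <- evaluate_solution(sol, fm, "knn", cv, cache)
  want <- crossval_evaluate(fm, NULL, classifier_spec("knn", 3), cv)$accuracy
  expect_equal(got$accuracy, want)
  again <- evaluate_solution(sol, fm, "knn", cv, cache)
  expect_identical(again$accuracy, got$accuracy)
})

hamming_objective <- function(target) {
  C <- length(target)
  function(genes, param) 100 * (1 - sum(genes != target) / C)
}

test_that("any returned front is mutually non-dominated, even at tiny budgets", {
  obj <- hamming_objective(c(rep(1L, 4), rep(0L, 15)))
  fr <- nsga2_run(objective = obj, n_channels = 19,
                  cfg = moo_config(8, 1, seed = 2))
  objs <- eegselect:::pop_objs(fr$solutions)
  expect_equal(oracle_fronts(objs)[[1]], seq_len(nrow(objs)))
})

test_that("all three optimisers recover a planted 4-channel optimum", {
  set.seed(1)
  target <- integer(19); target[c(2, 7, 11, 17)] <- 1L
  obj <- hamming_objective(target)
  for (runner in list(nsga2_run, nsga3_run, mopso_run)) {
    for (seed in 1:2) {
      fr <- runner(objective = obj, n_channels = 19,
                   cfg = moo_config(40, 30, seed = seed))
      best <- max(vapply(fr$solutions, `[[`, 0, "ca"))
      expect_equal(best, 100)
      hit <- Filter(function(s) s$ca == 100, fr$solutions)[[1]]
      expect_equal(hit$genes, target)
    }
  }
})

test_that("archive accuracy per channel count never degrades over generations", {
  obj <- hamming_objective(c(rep(1L, 3), rep(0L, 13)))
  for (runner in list(nsga2_run, nsga3_run)) {
    fr <- runner(objective = obj, n_channels = 16,
                 cfg = moo_config(20, 15, seed = 5))
    best_at <- function(summary) tapply(summary$accuracy, summary$no_ch, max)
    for (g in 2:length(fr$history)) {
      prev <- best_at(fr$history[[g - 1]])
      curr <- best_at(fr$history[[g]])
      shared <- intersect(names(prev), names(curr))
      expect_true(all(curr[shared] >= prev[shared]))
    }
  }
})

test_that("every emitted solution satisfies the encoding invariants", {
  obj <- hamming_objective(c(rep(1L, 2), rep(0L, 10)))
  fr <- mopso_run(objective = obj, n_channels = 12, prange = c(1L, 10L),
                  cfg = moo_config(12, 8, seed = 3))
  for (s in fr$solutions) {
    expect_gte(sum(s$genes), 1L)
    expect_equal(s$no_ch, sum(s$genes))
    expect_true(all(s$genes %in% c(0L, 1L)))
    expect_true(s$param >= 1L && s$param <= 10L)
    expect_lte(s$ca, 100)
  }
})

test_that("runs are reproducible from their seed", {
  obj <- hamming_objective(c(1L, 1L, rep(0L, 8)))
  a <- nsga2_run(objective = obj, n_channels = 10,
                 cfg = moo_config(10, 6, seed = 12))
  b <- nsga2_run(objective = obj, n_channels = 10,
                 cfg = moo_config(10, 6, seed = 12))
  expect_identical(a$solutions, b$solutions)
  expect_identical(a$history, b$history)
})

test_that("optimisation over a real feature matrix finds the informative channel", {
  fm <- toy_fm(n = 60, channels = c("A", "B", "C", "D"), informative = "D",
               shift = 4, seed = 2)
  fr <- nsga2_run(fm, "knn", moo_config(12, 10, seed = 4), cv_config(5, 8))
  df <- as.data.frame(fr)
  one <- df[df$no_ch == 1, ]
  expect_equal(one$channels[which.max(one$accuracy)], "D")
  expect_gt(max(df$accuracy), 90)
})
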