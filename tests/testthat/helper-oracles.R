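# Independent oracles and fixture builders shared across tests. The
# oracles deliberately use naive per-sample loops / pairwise scans so
# they share no code path with the implementation they check.

# direct-summation implementations of the seven measures
oracle_measure <- function(x, measure, alpha = 0.2, p = 1.1, thr = 3,
                           eps = 1e-12) {
  n <- length(x)
  acc <- 0
  switch(measure,
    Eng = { for (v in x) acc <- acc + v * v; acc },
    BP = { for (v in x) acc <- acc + v * v; log(max(acc / n, eps)) },
    ThEn = { k <- 0L; for (v in x) if (abs(v) > alpha) k <- k + 1L; k },
    NoEn = { for (v in x) acc <- acc + abs(v)^p; acc },
    SuEn = {
      cnt <- 0L; s <- 0
      for (v in x) {
        if (abs(v) <= thr) cnt <- cnt + 1L
        s <- s + min(v * v, thr * thr)
      }
      n - cnt + s
    },
    LogEn = { for (v in x) acc <- acc + log(v * v + eps); acc },
    TShEn = { for (v in x) acc <- acc + (v * v + eps) * log(v * v + eps); acc / n })
}

# brute-force non-dominated fronts by repeated pairwise scanning
oracle_fronts <- function(objs) {
  objs <- as.matrix(objs)
  dom <- function(a, b) {
    objs[a, 1] >= objs[b, 1] && objs[a, 2] <= objs[b, 2] &&
      (objs[a, 1] > objs[b, 1] || objs[a, 2] < objs[b, 2])
  }
  idx <- seq_len(nrow(objs))
  fronts <- list()
  while (length(idx) > 0L) {
    nd <- idx[vapply(idx, function(i) {
      !any(vapply(idx, function(j) j != i && dom(j, i), TRUE))
    }, TRUE)]
    fronts[[length(fronts) + 1L]] <- sort(nd)
    idx <- setdiff(idx, nd)
  }
  fronts
}

# two-sided periodogram band power (independent FFT route)
fft_band_power <- function(x, fs, lo, hi) {
  sp <- Mod(stats::fft(x))^2 / length(x)
  f <- (seq_along(x) - 1) * fs / length(x)
  sel <- f >= lo & f < hi
  sum(sp[sel])
}

# counting mock evaluator over a fixed channel universe
mock_evaluator <- function(channels, score_fn = function(ch) length(ch)) {
  n <- 0L
  f <- function(ch) {
    n <<- n + 1L
    score_fn(ch)
  }
  attr(f, "count") <- function() n
  attr(f, "channels") <- channels
  f
}

# feature matrix built directly (no signal pipeline): optional channel
# whose 6 columns carry a class shift
toy_fm <- function(n = 60L, channels = c("A", "B", "C"), informative = "B",
                   shift = 3, seed = 1L, measure = "Eng") {
  stopifnot(n %% 2L == 0L)
  set.seed(seed)
  labels <- rep(c("HC", "MCI"), each = n %/% 2L)
  vals <- matrix(rnorm(n * 6L * length(channels)), nrow = n)
  if (!is.null(informative)) {
    ci <- which(channels == informative)
    cols <- ((ci - 1L) * 6L + 1L):(ci * 6L)
    vals[labels == "MCI", cols] <- vals[labels == "MCI", cols] + shift
  }
  eegselect:::new_feature_matrix(vals, labels,
                                 paste0("S", rep(seq_len(n %/% 6L + 1L),
                                                 each = 6L)[seq_len(n)]),
                                 channels, measure)
}

# small planted-effect cohort feature matrix (shared by several tests)
small_cohort_fm <- function(n_per_class = 5L, duration_s = 20, effect = 3,
                            seed = 11L, measure = "BP",
                            planted = c("Fp1", "T6", "O2")) {
  cfg <- cohort_config(n_hc = n_per_class, n_mci = n_per_class,
                       duration_s = duration_s, fs = 256,
                       planted_channels = planted, effect_size = effect,
                       seed = seed)
  cohort_feature_matrix(cfg, measure)
}

# 99% binomial acceptance band (percent) around the majority-class rate
chance_band <- function(n, majority_rate = 0.5) {
  halfwidth <- stats::qnorm(0.995) * sqrt(majority_rate * (1 - majority_rate) / n)
  100 * c(majority_rate - halfwidth, majority_rate + halfwidth)
}
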