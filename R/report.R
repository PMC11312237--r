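#' Feature matrix of a synthetic cohort, one subject at a time
#'
#' Convenience pipeline: generate each subject of `cfg`, band-pass
#' filter, segment, and extract wavelet features, discarding raw signals
#' as it goes so that a full-size cohort never has to be held in memory.
#'
#' @param cfg A [cohort_config()].
#' @param measure Measure code, see [compute_measure()].
#' @param params A [measure_params()].
#' @param low_hz,high_hz,order Band-pass settings, see
#'   [bandpass_filter()].
#' @param seg_len_s Segment length in seconds.
#' @return A `feature_matrix` covering all subjects' segments.
#' @export
cohort_feature_matrix <- function(cfg, measure = "ThEn",
                                  params = measure_params(),
                                  low_hz = 0.5, high_hz = 32, order = 5,
                                  seg_len_s = 10) {
  stopifnot(inherits(cfg, "cohort_config"))
  classes <- c(rep("HC", cfg$n_hc), rep("MCI", cfg$n_mci))
  blocks <- vector("list", length(classes))
  labels <- list(); subjects <- list()
  for (i in seq_along(classes)) {
    rec <- generate_subject(cfg, classes[i], i)
    rec <- bandpass_filter(rec, low_hz, high_hz, order)
    segs <- segment_recording(rec, seg_len_s)
    fm_i <- build_feature_matrix(segs, measure, params)
    blocks[[i]] <- fm_i$values
    labels[[i]] <- fm_i$labels
    subjects[[i]] <- fm_i$subject_ids
  }
  new_feature_matrix(do.call(rbind, blocks), unlist(labels), unlist(subjects),
                     cfg$channel_labels, measure)
}

#' Full-channel metrics table over measures and classifiers
#'
#' Evaluates every (measure, classifier) combination on all channels
#' under cross-validation and tabulates mean and fold-sd of accuracy,
#' sensitivity, specificity and F-score — the all-electrode baseline
#' that channel selection is judged against.
#'
#' @param segments List of [eeg_segment()] objects.
#' @param measures Character vector of measure codes.
#' @param specs List of [classifier_spec()] objects.
#' @param params A [measure_params()].
#' @param cv A [cv_config()].
#' @return data.frame, one row per measure x classifier, with columns
#'   `measure`, `family`, `param` and `<metric>_mean` / `<metric>_sd`.
#' @export
run_full_channel <- function(segments, measures = measure_names(),
                             specs = list(classifier_spec("knn", 3L)),
                             params = measure_params(), cv = cv_config()) {
  rows <- list()
  for (m in measures) {
    fm <- build_feature_matrix(segments, m, params)
    for (sp in specs) {
      res <- crossval_evaluate(fm, NULL, sp, cv)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, family = sp$family, param = sp$param,
        accuracy_mean = res$accuracy, accuracy_sd = res$accuracy_sd,
        sensitivity_mean = res$sensitivity, sensitivity_sd = res$sensitivity_sd,
        specificity_mean = res$specificity, specificity_sd = res$specificity_sd,
        f_score_mean = res$f_score, f_score_sd = res$f_score_sd,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Channel-selection frequency across methods
#'
#' Counts how often each channel appears in the selected subsets of one
#' or more selection results (greedy traces and/or Pareto fronts),
#' restricted to subsets whose size lies in `sizes`. The per-channel
#' counts reveal which electrodes the methods agree on.
#'
#' @param results A `selection_trace`, a `pareto_front`, or a list of
#'   them.
#' @param sizes Integer vector of subset sizes to count (default 2:10).
#' @param channel_labels Channel universe for the output order; default
#'   the union encountered.
#' @return data.frame with columns `channel` and `count`, in
#'   `channel_labels` order.
#' @export
channel_selection_frequency <- function(results, sizes = 2:10,
                                        channel_labels = NULL) {
  if (inherits(results, c("selection_trace", "pareto_front"))) {
    results <- list(results)
  }
  subsets <- list()
  for (r in results) {
    if (inherits(r, "selection_trace")) {
      subsets <- c(subsets, lapply(r$iterations, `[[`, "channels"))
    } else if (inherits(r, "pareto_front")) {
      labs <- r$channel_labels %||% as.character(seq_along(r$solutions[[1L]]$genes))
      subsets <- c(subsets, lapply(r$solutions, function(s) labs[s$genes == 1L]))
    } else {
      stop("unsupported result type: ", class(r)[1L], call. = FALSE)
    }
  }
  subsets <- subsets[vapply(subsets, length, 0L) %in% sizes]
  if (is.null(channel_labels)) {
    channel_labels <- unique(unlist(subsets))
  }
  counts <- vapply(channel_labels, function(ch)
    sum(vapply(subsets, function(s) ch %in% s, TRUE)), 0L)
  data.frame(channel = channel_labels, count = unname(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}
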