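# Wrapper channel selection: the search objective is the cross-validated
# accuracy of a classifier restricted to the candidate channels. The CV
# fold seed is held fixed across all evaluations inside one search so
# subset comparisons are paired.

# evaluator: function(channel labels) -> accuracy (%); counts calls
make_cv_evaluator <- function(fm, spec, cv) {
  force(fm); force(spec); force(cv)
  n_calls <- 0L
  f <- function(channels) {
    n_calls <<- n_calls + 1L
    crossval_evaluate(fm, channel_columns(fm, channels), spec, cv)$accuracy
  }
  attr(f, "count") <- function() n_calls
  f
}

evaluator_count <- function(evaluator) {
  cnt <- attr(evaluator, "count")
  if (is.null(cnt)) NA_integer_ else cnt()
}

new_selection_trace <- function(method, iterations, evaluations) {
  structure(list(method = method, iterations = iterations,
                 evaluations_performed = evaluations),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %s: %d iterations, %d evaluations\n",
              x$method, length(x$iterations), x$evaluations_performed))
  best <- which.max(vapply(x$iterations, `[[`, 0, "accuracy"))
  it <- x$iterations[[best]]
  cat(sprintf("  best: CA %.2f%% with %d channels (%s)\n", it$accuracy,
              length(it$channels), paste(it$channels, collapse = ", ")))
  invisible(x)
}

#' Summarise a selection trace as a data frame
#' @param x A `selection_trace`.
#' @param ... Unused.
#' @return data.frame with columns `size`, `accuracy`, `channels`
#'   (comma-separated labels).
#' @export
as.data.frame.selection_trace <- function(x, ...) {
  data.frame(
    size = vapply(x$iterations, function(i) length(i$channels), 0L),
    accuracy = vapply(x$iterations, `[[`, 0, "accuracy"),
    channels = vapply(x$iterations, function(i) paste(i$channels, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Greedy back-elimination of EEG channels
#'
#' Starts from the full channel set (evaluated once) and repeatedly
#' removes the single channel whose removal yields the highest
#' cross-validated accuracy, until one channel remains. With C channels
#' this records C iterations (subset sizes C, C-1, ..., 1) and performs
#' exactly C(C+1)/2 accuracy evaluations. Ties are broken in favour of
#' the candidate earliest in channel order.
#'
#' @param fm A `feature_matrix`.
#' @param spec A [classifier_spec()].
#' @param cv A [cv_config()]; its seed is shared by every evaluation.
#' @param evaluator Optional replacement objective
#'   `function(channels) -> accuracy`, mainly for algorithmic testing;
#'   default is cross-validated accuracy on `fm`.
#' @return A `selection_trace` whose `iterations` list the best subset
#'   and accuracy at each size.
#' @export
backward_eliminate <- function(fm, spec = classifier_spec("knn", 3L),
                               cv = cv_config(), evaluator = NULL) {
  channels <- if (is.null(evaluator)) fm$channel_labels else
    attr(evaluator, "channels") %||% fm$channel_labels
  if (length(channels) < 2L) stop("need at least 2 channels", call. = FALSE)
  if (is.null(evaluator)) evaluator <- make_cv_evaluator(fm, spec, cv)

  current <- channels
  iterations <- list(list(channels = current, accuracy = evaluator(current)))
  while (length(current) > 1L) {
    accs <- vapply(seq_along(current),
                   function(i) evaluator(current[-i]), 0)
    drop_i <- which.max(accs)         # first max in channel order
    current <- current[-drop_i]
    iterations[[length(iterations) + 1L]] <-
      list(channels = current, accuracy = accs[drop_i])
  }
  new_selection_trace("backward_elimination", iterations,
                      evaluator_count(evaluator))
}

#' Greedy forward-addition of EEG channels
#'
#' Mirror of [backward_eliminate()]: iteration 1 evaluates every single
#' channel, each later iteration adds the channel that maximises
#' accuracy, ending at the full set. C channels again cost exactly
#' C(C+1)/2 evaluations over C iterations (sizes 1 .. C).
#'
#' @inheritParams backward_eliminate
#' @return A `selection_trace`.
#' @export
forward_add <- function(fm, spec = classifier_spec("knn", 3L),
                        cv = cv_config(), evaluator = NULL) {
  channels <- if (is.null(evaluator)) fm$channel_labels else
    attr(evaluator, "channels") %||% fm$channel_labels
  if (length(channels) < 1L) stop("need at least 1 channel", call. = FALSE)
  if (is.null(evaluator)) evaluator <- make_cv_evaluator(fm, spec, cv)

  current <- character(0)
  remaining <- channels
  iterations <- list()
  while (length(remaining) > 0L) {
    accs <- vapply(remaining, function(ch) evaluator(c(current, ch)), 0)
    add_i <- which.max(accs)
    current <- c(current, remaining[add_i])
    remaining <- remaining[-add_i]
    iterations[[length(iterations) + 1L]] <-
      list(channels = current, accuracy = unname(accs[add_i]))
  }
  new_selection_trace("forward_addition", iterations,
                      evaluator_count(evaluator))
}

#' Single-channel accuracy ranking and incremental subsets
#'
#' `single_channel_ranking()` scores every channel used alone;
#' `incremental_subsets()` then evaluates the cumulative top-1, top-2,
#' ..., top-C subsets of that ranking — the simple incremental-evaluation
#' baseline that greedy and multi-objective selection are compared
#' against.
#'
#' @inheritParams backward_eliminate
#' @return `single_channel_ranking()`: data.frame with columns `channel`
#'   and `accuracy`, sorted by decreasing accuracy (ties keep channel
#'   order). `incremental_subsets()`: a `selection_trace` with subset
#'   sizes 1 .. C.
#' @export
single_channel_ranking <- function(fm, spec = classifier_spec("knn", 3L),
                                   cv = cv_config(), evaluator = NULL) {
  channels <- if (is.null(evaluator)) fm$channel_labels else
    attr(evaluator, "channels") %||% fm$channel_labels
  if (is.null(evaluator)) evaluator <- make_cv_evaluator(fm, spec, cv)
  accs <- vapply(channels, function(ch) evaluator(ch), 0)
  ord <- order(-accs, seq_along(accs))
  data.frame(channel = channels[ord], accuracy = unname(accs[ord]),
             stringsAsFactors = FALSE)
}

#' @param ranking Result of `single_channel_ranking()`.
#' @rdname single_channel_ranking
#' @export
incremental_subsets <- function(ranking, fm, spec = classifier_spec("knn", 3L),
                                cv = cv_config(), evaluator = NULL) {
  if (is.null(evaluator)) evaluator <- make_cv_evaluator(fm, spec, cv)
  iterations <- lapply(seq_len(nrow(ranking)), function(k) {
    subset <- ranking$channel[seq_len(k)]
    list(channels = subset, accuracy = evaluator(subset))
  })
  new_selection_trace("incremental", iterations, evaluator_count(evaluator))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
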