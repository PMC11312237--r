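#' Specify a classifier family and its integer hyperparameter
#'
#' One integer `param` tunes each family, mirroring the single parameter
#' gene used by the channel-selection optimisers: KNN neighbours K in
#' 1-10; SVM kernel 1 = linear, 2 = polynomial (degree 3), 3 = RBF;
#' discriminant analysis 1 = linear, 2 = quadratic; random forest
#' maximum tree depth in 1-35.
#'
#' @param family `"knn"`, `"svm"`, `"da"` or `"rf"`.
#' @param param Integer hyperparameter within the family's range.
#' @return An object of class `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("knn", 3)
classifier_spec <- function(family = c("knn", "svm", "da", "rf"), param = 1L) {
  family <- match.arg(family)
  param <- as.integer(param)
  rng <- param_range(family)
  if (param < rng[1L] || param > rng[2L]) {
    stop(sprintf("`param` for %s must lie in [%d, %d]", family, rng[1L], rng[2L]),
         call. = FALSE)
  }
  structure(list(family = family, param = param), class = "classifier_spec")
}

# admissible integer range of the parameter gene per family
param_range <- function(family) {
  switch(family,
         knn = c(1L, 10L), svm = c(1L, 3L), da = c(1L, 2L), rf = c(1L, 35L))
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s (param = %d)\n", x$family, x$param))
  invisible(x)
}

#' Cross-validation settings
#'
#' @param k_folds Number of folds (default 10).
#' @param seed Seed for the fold assignment (and any stochastic
#'   classifier components); the same seed always yields the same folds.
#' @param grouped If `TRUE`, folds partition subjects rather than
#'   segments, so no subject contributes to both training and validation
#'   of a fold. The default (`FALSE`) is segment-level cross-validation.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(k_folds = 10L, seed = 1L, grouped = FALSE) {
  stopifnot(k_folds >= 2L)
  structure(list(k_folds = as.integer(k_folds), seed = as.integer(seed),
                 grouped = isTRUE(grouped)),
            class = "cv_config")
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, sensitivity (recall), specificity, precision and
#' F-score as percentages, with MCI as the positive class. A metric
#' whose denominator is zero is reported as `NA` (undefined), never as
#' zero, and listed in the `undefined` element.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts (total > 0).
#' @return List with elements `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f_score` (percent or `NA`) and `undefined`
#'   (character vector of undefined metric names).
#' @export
#' @examples
#' confusion_metrics(tp = 50, tn = 40, fp = 10, fn = 0)
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop("confusion counts sum to zero", call. = FALSE)
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  acc <- 100 * (tp + tn) / total
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f <- if (!is.na(sens) && !is.na(prec) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  out <- list(accuracy = acc, sensitivity = sens, specificity = spec,
              precision = prec, f_score = f)
  out$undefined <- names(out)[vapply(out, function(v) is.na(v[1L]), TRUE)]
  out
}

# Stratified fold assignment: within-class shuffling, round-robin fold
# labels continuing across classes so overall fold sizes differ by <= 1.
make_folds <- function(labels, k, grouped = FALSE, subject_ids = NULL) {
  n <- length(labels)
  folds <- integer(n)
  if (grouped) {
    subj <- unique(subject_ids)
    if (length(subj) < k) stop("fewer subjects than folds", call. = FALSE)
    sf <- integer(length(subj))
    counter <- 0L
    for (cl in unique(labels[match(subj, subject_ids)])) {
      idx <- which(vapply(subj, function(s)
        labels[match(s, subject_ids)] == cl, TRUE))
      idx <- idx[sample.int(length(idx))]
      sf[idx] <- (counter + seq_along(idx) - 1L) %% k + 1L
      counter <- counter + length(idx)
    }
    folds <- sf[match(subject_ids, subj)]
  } else {
    counter <- 0L
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- (counter + seq_along(idx) - 1L) %% k + 1L
      counter <- counter + length(idx)
    }
  }
  folds
}

# KNN with deterministic tie-breaking: majority vote among the k nearest
# training rows; a tied vote is resolved by the single nearest
# neighbour's class. Distances are Euclidean.
knn_predict <- function(train, test, cl, k) {
  k <- min(k, nrow(train))
  tr2 <- rowSums(train^2)
  te2 <- rowSums(test^2)
  # squared distances: |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(te2, tr2, "+") - 2 * tcrossprod(test, train)
  classes <- sort(unique(cl))
  apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]
    votes <- table(factor(cl[nn], levels = classes))
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else as.character(cl[nn[1L]])
  })
}

# median-distance heuristic for the RBF bandwidth, on <= 200 training rows
rbf_gamma <- function(train) {
  n <- nrow(train)
  idx <- if (n > 200L) sort(sample.int(n, 200L)) else seq_len(n)
  d <- stats::dist(train[idx, , drop = FALSE])
  med <- stats::median(d[d > 0])
  if (!is.finite(med) || med <= 0) return(1 / max(1L, ncol(train)))
  1 / (2 * med^2)
}

# train on (train, cl), predict labels of test; both already standardized
fit_predict <- function(train, test, cl, spec) {
  cl <- factor(cl)
  switch(spec$family,
    knn = knn_predict(train, test, as.character(cl), spec$param),
    svm = {
      kern <- c("linear", "polynomial", "radial")[spec$param]
      args <- list(x = train, y = cl, kernel = kern, scale = FALSE, cost = 1)
      if (kern == "polynomial") args$degree <- 3
      if (kern == "radial") args$gamma <- rbf_gamma(train)
      fit <- do.call(e1071::svm, args)
      as.character(predict(fit, test))
    },
    da = {
      fit <- if (spec$param == 1L) MASS::lda(train, grouping = cl)
             else MASS::qda(train, grouping = cl)
      as.character(predict(fit, test)$class)
    },
    rf = {
      colnames(train) <- colnames(test) <- paste0("V", seq_len(ncol(train)))
      df <- data.frame(.y = cl, train, check.names = FALSE)
      fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                            num.trees = 100L, max.depth = spec$param,
                            seed = sample.int(.Machine$integer.max, 1L),
                            num.threads = 1L)
      as.character(predict(fit, data.frame(test, check.names = FALSE),
                           num.threads = 1L)$predictions)
    })
}

#' Cross-validated evaluation of a classifier on a feature matrix
#'
#' Stratified k-fold cross-validation (default 10-fold): folds are drawn
#' once from `cv$seed`; within each round the features are z-scored with
#' means and standard deviations fitted on the training part only,
#' zero-variance columns are dropped, the classifier is trained and the
#' held-out rows predicted. Metrics are computed per fold with MCI as
#' the positive class and averaged over folds.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param column_mask Optional logical/integer selection of feature
#'   columns (e.g. from [channel_columns()]); default all.
#' @param spec A [classifier_spec()].
#' @param cv A [cv_config()].
#' @return An object of class `cv_result`: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f_score` (fold means, percent),
#'   the corresponding `*_sd` fold standard deviations,
#'   `per_fold` (data.frame), and `confusion_totals` (tp/tn/fp/fn summed
#'   over folds).
#' @export
crossval_evaluate <- function(fm, column_mask = NULL, spec = classifier_spec("knn", 3L),
                              cv = cv_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(spec, "classifier_spec"),
            inherits(cv, "cv_config"))
  x <- fm$values
  if (!is.null(column_mask)) x <- x[, column_mask, drop = FALSE]
  if (ncol(x) < 1L) stop("column mask selects no features", call. = FALSE)
  y <- fm$labels
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (cv$k_folds > length(y)) {
    stop("k_folds (", cv$k_folds, ") exceeds the number of segments (",
         length(y), ")", call. = FALSE)
  }

  with_private_seed(cv$seed, {
    folds <- make_folds(y, cv$k_folds, cv$grouped, fm$subject_ids)
    per_fold <- vector("list", cv$k_folds)
    totals <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    for (f in seq_len(cv$k_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) {
        stop("a class is absent from the training part of fold ", f, call. = FALSE)
      }
      mu <- colMeans(x[tr, , drop = FALSE])
      sdev <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
      keep <- sdev > 0
      if (!any(keep)) stop("all selected features are constant", call. = FALSE)
      xs <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep]), 2L,
                  sdev[keep], "/")
      pred <- fit_predict(xs[tr, , drop = FALSE], xs[!tr, , drop = FALSE],
                          y[tr], spec)
      truth <- y[!tr]
      tp <- sum(pred == "MCI" & truth == "MCI")
      tn <- sum(pred != "MCI" & truth != "MCI")
      fp <- sum(pred == "MCI" & truth != "MCI")
      fn <- sum(pred != "MCI" & truth == "MCI")
      totals <- totals + c(tp, tn, fp, fn)
      m <- confusion_metrics(tp, tn, fp, fn)
      per_fold[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                                  sensitivity = m$sensitivity,
                                  specificity = m$specificity,
                                  precision = m$precision,
                                  f_score = m$f_score,
                                  tp = tp, tn = tn, fp = fp, fn = fn)
    }
    per_fold <- do.call(rbind, per_fold)
    res <- list(per_fold = per_fold,
                confusion_totals = as.list(totals))
    for (metric in c("accuracy", "sensitivity", "specificity", "precision",
                     "f_score")) {
      res[[metric]] <- mean(per_fold[[metric]], na.rm = TRUE)
      res[[paste0(metric, "_sd")]] <- stats::sd(per_fold[[metric]], na.rm = TRUE)
    }
    structure(res, class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> CA %.2f%% (sd %.2f) | sens %.2f | spec %.2f | F %.2f\n",
              x$accuracy, x$accuracy_sd, x$sensitivity, x$specificity,
              x$f_score))
  invisible(x)
}

#' Map channel selections to feature-matrix columns
#'
#' All six feature columns of a channel toggle together.
#'
#' @param fm A `feature_matrix`.
#' @param channels Character vector of channel labels, or a
#'   logical/0-1 vector over `fm$channel_labels`.
#' @return Logical vector over the columns of `fm$values`.
#' @export
channel_columns <- function(fm, channels) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.character(channels)) {
    bad <- setdiff(channels, fm$channel_labels)
    if (length(bad)) stop("unknown channels: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    sel <- channels
  } else {
    stopifnot(length(channels) == length(fm$channel_labels))
    sel <- fm$channel_labels[as.logical(channels)]
  }
  fm$column_meta$channel %in% sel
}
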