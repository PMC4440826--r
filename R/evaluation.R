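#' Stratified train/test split
#'
#' Randomly partitions a labelled cohort into training and test sets at a
#' fixed fraction, stratified by class so each class contributes
#' `round(n_class * train_fraction)` training records (within one subject of
#' the target fraction). `train_counts` overrides the per-class training
#' sizes exactly, e.g. `c("0" = 125, "1" = 115)` to reproduce a historical
#' 115/125 split of 145 patients and 155 controls.
#'
#' @param data Labelled data frame.
#' @param label Name of the 0/1 (or factor) class column.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 4/5).
#' @param stratified Stratify by class (default `TRUE`).
#' @param seed Integer seed.
#' @param train_counts Optional named vector of exact per-class training
#'   counts.
#' @return A list with tibbles `train` and `test`; together they partition
#'   `data`.
#' @export
split_cohort <- function(data, label = "class", train_fraction = 0.8,
                         stratified = TRUE, seed = 1L, train_counts = NULL) {
  if (!label %in% names(data)) {
    param_error(sprintf("Label column '%s' not found.", label))
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    param_error("`train_fraction` must lie strictly between 0 and 1.")
  }
  cls <- as.character(data[[label]])
  if (stratified && any(table(cls) < 2)) {
    param_error("Each class must have at least 2 members for a stratified split.")
  }
  set.seed(derive_seed(seed, 211L))
  n <- nrow(data)
  if (!stratified) {
    k <- round(n * train_fraction)
    idx <- sample.int(n, k)
  } else {
    idx <- integer(0)
    for (c in sort(unique(cls))) {
      rows <- which(cls == c)
      k <- if (!is.null(train_counts) && c %in% names(train_counts)) {
        train_counts[[c]]
      } else {
        round(length(rows) * train_fraction)
      }
      if (k < 1 || k >= length(rows)) {
        param_error(sprintf("Class '%s' cannot supply %d training records.",
                            c, k))
      }
      idx <- c(idx, sample(rows, k))
    }
  }
  list(train = tibble::as_tibble(data[sort(idx), , drop = FALSE]),
       test = tibble::as_tibble(data[setdiff(seq_len(n), idx), , drop = FALSE]))
}

#' Full classification metric panel
#'
#' The confusion-matrix rates plus the score-regression diagnostics
#' conventionally reported alongside them: accuracy `(TP+TN)/N`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, error
#' `1 - accuracy`, and, on the raw scores against the 0/1 labels, the
#' Pearson correlation coefficient (CC), MSE, RMSE, MAE, relative absolute
#' error `RAE = sum(|e|) / sum(|label - mean(label)|)` and relative squared
#' error `RSE = sum(e^2) / sum((label - mean(label))^2)`. With
#' zero-variance labels CC is undefined and reported as `NA`.
#'
#' Scores are optionally clipped to \[0, 1\] before the regression metrics
#' (`clip_scores = TRUE`, the convention of the tool family this mirrors,
#' where model output is interpreted as a class probability); thresholded
#' classes are never used for them.
#'
#' @param labels 0/1 vector, `1` = patient.
#' @param scores Numeric classifier scores (higher = more patient-like).
#' @param threshold Rounding threshold for the hard classification.
#' @param clip_scores Clip scores into \[0, 1\] for the regression metrics.
#' @return A one-row tibble with counts and all metrics.
#' @export
#' @examples
#' panel_metrics(c(1, 1, 0, 0), c(0.9, 0.6, 0.4, 0.1))
panel_metrics <- function(labels, scores, threshold = 0.5,
                          clip_scores = TRUE) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    param_error("`labels` and `scores` must have equal length.")
  }
  pred <- as.integer(is.finite(scores) & scores >= threshold)
  cc <- confusion_counts(labels, pred)
  n <- length(labels)
  s <- if (clip_scores) pmin(pmax(scores, 0), 1) else scores
  s[!is.finite(s)] <- threshold  # neutral score for invalid records
  e <- s - labels
  denom_abs <- sum(abs(labels - mean(labels)))
  denom_sq <- sum((labels - mean(labels))^2)
  tibble::tibble(
    tp = cc$tp, fn = cc$fn, tn = cc$tn, fp = cc$fp,
    accuracy = (cc$tp + cc$tn) / n,
    sensitivity = if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_,
    specificity = if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else NA_real_,
    error = 1 - (cc$tp + cc$tn) / n,
    cc = if (sd(labels) > 0 && sd(s) > 0) cor(s, labels) else NA_real_,
    mse = mean(e^2),
    rmse = sqrt(mean(e^2)),
    mae = mean(abs(e)),
    rae = if (denom_abs > 0) sum(abs(e)) / denom_abs else NA_real_,
    rse = if (denom_sq > 0) sum(e^2) / denom_sq else NA_real_
  )
}

#' ROC curve by threshold sweep
#'
#' Sweeps the classification threshold over the unique scores, recording
#' (FPR, TPR) at each, and integrates the trapezoidal AUC. The
#' higher-score-is-positive orientation is preserved, so a marker that is
#' lower in cases legitimately yields AUC < 0.5; the AUC equals the
#' Mann-Whitney `U/(n1*n2)` identity with midranks.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 vector, `1` = positive.
#' @return A `gep_roc` object: tibble of `threshold`, `fpr`, `tpr` points
#'   with the `auc` attribute; supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    param_error("`scores` and `labels` must have equal length.")
  }
  if (any(!is.finite(scores))) {
    warn(sprintf("Dropping %d record(s) with non-finite scores from the ROC sweep.",
                 sum(!is.finite(scores))))
    labels <- labels[is.finite(scores)]
    scores <- scores[is.finite(scores)]
  }
  if (length(unique(labels)) < 2) {
    param_error("ROC analysis needs both classes present.")
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble::tibble(threshold = t,
                   fpr = sum(pred & labels == 0) / n0,
                   tpr = sum(pred & labels == 1) / n1)
  })
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(pts, auc = auc, class = c("gep_roc", class(pts)))
}

#' @describeIn roc_curve The (threshold, FPR, TPR) points as a tibble.
#' @param x A `gep_roc`.
#' @param ... Unused.
#' @export
tidy.gep_roc <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("threshold", "fpr", "tpr")])
}

#' @describeIn roc_curve One-row tibble with the AUC.
#' @export
glance.gep_roc <- function(x, ...) tibble::tibble(auc = attr(x, "auc"))

#' @describeIn roc_curve ROC plot with the chance diagonal.
#' @param object A `gep_roc`.
#' @export
autoplot.gep_roc <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc")))
}

label_cases <- function(data, positive, negative) {
  data <- dplyr::filter(data, .data$group %in% c(positive, negative))
  data$class <- as.integer(data$group == positive)
  data
}

#' Run a train/test classification experiment
#'
#' Orchestrates the full pipeline: optionally filter the cohort (e.g. by
#' disease stage), label the case and control groups, split train/test,
#' obtain scores from a published classifier or by evolving a fresh GEP
#' model on the training set, and compute the metric panel on both sets.
#' With `replicates > 1` the experiment repeats with distinct derived seeds
#' (e.g. in triplicate) and the replicate with the best training accuracy
#' is flagged.
#'
#' @param data Cohort data frame.
#' @param model `"published1"`, `"published2"`, a `gep_fit`, or a
#'   [gep_params()] object (a fresh model is then evolved per replicate).
#' @param positive,negative Group labels forming the positive and negative
#'   class (defaults `"SCLC"` vs `"CONTROL"`).
#' @param stage Optional stage filter applied to the positive group
#'   (`"LIMITED"`, `"EXTENSIVE"`, `"I"`, `"II"`).
#' @param n_negative Optional number of negative-class records to subsample
#'   (seeded) before splitting, e.g. matching controls to cases.
#' @param train_fraction,train_counts,seed Passed to [split_cohort()].
#' @param threshold Rounding threshold.
#' @param scaling `"none"` or `"minmax"` (fitted on the training set).
#' @param replicates Number of repeats with derived seeds.
#' @return A tibble with one row per replicate and set (`train`/`test`):
#'   sizes, confusion counts, the metric panel, and `best` flagging the
#'   replicate with the highest training accuracy.
#' @export
run_experiment <- function(data, model = "published1", positive = "SCLC",
                           negative = "CONTROL", stage = NULL,
                           n_negative = NULL, train_fraction = 0.8,
                           train_counts = NULL, seed = 1L, threshold = 0.5,
                           scaling = c("none", "minmax"), replicates = 1L) {
  check_cohort(data)
  scaling <- match.arg(scaling)
  if (!is.null(stage)) {
    keep <- data$group != positive |
      (!is.na(data$stage) & data$stage == stage)
    data <- data[keep, , drop = FALSE]
  }
  labelled <- label_cases(data, positive, negative)
  one_rep <- function(rep_i) {
    rep_seed <- derive_seed(seed, 300L + rep_i)
    lab <- labelled
    if (!is.null(n_negative)) {
      neg_rows <- which(lab$class == 0L)
      if (n_negative > length(neg_rows)) {
        param_error("`n_negative` exceeds the available negative records.")
      }
      set.seed(derive_seed(rep_seed, 1L))
      drop <- setdiff(neg_rows, sample(neg_rows, n_negative))
      if (length(drop) > 0) lab <- lab[-drop, , drop = FALSE]
    }
    sp <- split_cohort(lab, "class", train_fraction, TRUE, rep_seed,
                       train_counts)
    sc <- if (scaling == "minmax") fit_marker_scaling(sp$train) else NULL
    score_fun <- if (identical(model, "published1")) {
      function(d) score_published(d, 1, threshold, sc)$score
    } else if (identical(model, "published2")) {
      function(d) score_published(d, 2, threshold, sc)$score
    } else if (inherits(model, "gep_fit")) {
      function(d) predict(model, apply_marker_scaling(d, sc), "score")
    } else if (inherits(model, "gep_params")) {
      fit <- gep_evolve(apply_marker_scaling(sp$train, sc),
                        label = "class", params = model, seed = rep_seed)
      function(d) predict(fit, apply_marker_scaling(d, sc), "score")
    } else {
      param_error("`model` must be 'published1', 'published2', a gep_fit or gep_params.")
    }
    purrr::map_dfr(c(train = "train", test = "test"), function(set) {
      d <- sp[[set]]
      dplyr::bind_cols(
        tibble::tibble(replicate = rep_i, set = set, n = nrow(d)),
        panel_metrics(d$class, score_fun(d), threshold)
      )
    })
  }
  out <- purrr::map_dfr(seq_len(replicates), one_rep)
  train_acc <- dplyr::filter(out, .data$set == "train")
  best_rep <- train_acc$replicate[which.max(train_acc$accuracy)]
  dplyr::mutate(out, best = .data$replicate == best_rep)
}
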