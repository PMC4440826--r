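# Safe vectorized semantics of the function set. Division by zero, Log or
# Sqrt outside their domain, Inv of zero and arithmetic overflow all
# propagate as non-finite values (the NON_FINITE sentinel); Exp and Logi
# clamp their argument to +-700 first, so they are total.
apply_fun <- function(id, a, b) {
  switch(id,
         a + b,                       # 1 "+"
         a - b,                       # 2 "-"
         a * b,                       # 3 "*"
         a / b,                       # 4 "/"
         exp(clamp_exp(a)),           # 5 "Exp"
         suppressWarnings(sqrt(a)),   # 6 "Sqrt"
         suppressWarnings(log10(a)),  # 7 "Log"
         1 / (1 + exp(clamp_exp(-a))),# 8 "Logi"
         1 / a)                       # 9 "Inv"
}

#' Evaluate a decoded expression tree
#'
#' Evaluates a `gep_tree` over a numeric matrix of inputs (one row per
#' record, one column per terminal, in terminal order). Children always have
#' larger node indices than their parent under level-order decoding, so a
#' single reverse sweep evaluates the whole tree. Invalid arithmetic yields
#' non-finite values rather than errors.
#'
#' @param tree A `gep_tree` from `decode_gene()`.
#' @param X Numeric matrix of terminal values.
#' @return Numeric vector of length `nrow(X)`; non-finite entries mark
#'   records where evaluation left the function domains.
#' @keywords internal
eval_tree <- function(tree, X) {
  n_nodes <- length(tree$sym)
  nr <- nrow(X)
  vals <- vector("list", n_nodes)
  for (i in n_nodes:1) {
    s <- tree$sym[i]
    if (s > tree$n_fun) {
      vals[[i]] <- if (s == tree$const_id) rep(tree$value[i], nr) else
        unname(X[, tree$term[i]])
    } else {
      a <- vals[[tree$child1[i]]]
      b <- if (!is.na(tree$child2[i])) vals[[tree$child2[i]]] else NULL
      vals[[i]] <- apply_fun(s, a, b)
    }
  }
  vals[[1]]
}

# Numeric output of a chromosome: active gene outputs combined by the
# linking function (addition).
chromosome_scores <- function(chrom, X, structure) {
  y <- 0
  for (g in seq_len(chrom$active)) {
    y <- y + eval_tree(decode_gene(chrom$genes[[g]], structure), X)
  }
  y
}

#' Classify records with a chromosome
#'
#' Sums the active gene outputs through the linking function and thresholds:
#' a record with output `y >= threshold` is classified as the positive class
#' `1` (patient), otherwise `0`. Records whose output is non-finite are
#' classified `0` and flagged invalid.
#'
#' @param chrom A `gep_chromosome`.
#' @param X Numeric matrix of terminal values.
#' @param structure The gene structure.
#' @param threshold Finite rounding threshold.
#' @return A list with `class` (integer 0/1 vector), `score` (numeric) and
#'   `invalid` (logical).
#' @keywords internal
classify_chromosome <- function(chrom, X, structure, threshold = 0.5) {
  assert_scalar_number(threshold, "threshold")
  y <- chromosome_scores(chrom, X, structure)
  invalid <- !is.finite(y)
  cls <- as.integer(!invalid & y >= threshold)
  list(class = cls, score = y, invalid = invalid)
}

#' Confusion counts
#'
#' Tallies true/false positives and negatives of 0/1 predictions against 0/1
#' labels, the positive class being `1` (patient).
#'
#' @param truth Integer (or logical) vector of true labels.
#' @param predicted Integer (or logical) vector of predicted labels.
#' @return A tibble with columns `tp`, `fn`, `tn`, `fp`.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 0), c(1, 0, 0))
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    param_error("`truth` and `predicted` must have equal length.")
  }
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (any(!truth %in% c(0L, 1L)) || any(!predicted %in% c(0L, 1L))) {
    param_error("Labels and predictions must be 0/1.")
  }
  tibble::tibble(
    tp = sum(truth == 1L & predicted == 1L),
    fn = sum(truth == 1L & predicted == 0L),
    tn = sum(truth == 0L & predicted == 0L),
    fp = sum(truth == 0L & predicted == 1L)
  )
}

#' Accuracy fitness of a chromosome
#'
#' The fitness is the classification accuracy
#' `(TP + TN) / (TP + FN + TN + FP)`. A chromosome whose output is
#' non-finite on any record receives fitness 0, the simplest
#' selection-viable penalty for leaving the function domains.
#'
#' @param chrom A `gep_chromosome`.
#' @param X Numeric matrix of terminal values.
#' @param labels 0/1 vector, `1` = patient.
#' @param structure The gene structure.
#' @param threshold Rounding threshold.
#' @return A list with `fitness`, `confusion` (tibble), `n_invalid`.
#' @keywords internal
fitness_report <- function(chrom, X, labels, structure, threshold = 0.5) {
  if (nrow(X) == 0) param_error("Dataset must be non-empty.")
  labels <- as.integer(labels)
  if (any(!labels %in% c(0L, 1L))) param_error("Labels must be 0/1.")
  cl <- classify_chromosome(chrom, X, structure, threshold)
  cc <- confusion_counts(labels, cl$class)
  fit <- if (any(cl$invalid)) 0 else (cc$tp + cc$tn) / length(labels)
  list(fitness = fit, confusion = cc, n_invalid = sum(cl$invalid))
}
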