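#' Logistic sigmoid
#'
#' `aps_logi(x) = 1 / (1 + exp(-x))`, the unary sigmoid used as a function
#' symbol by the evolved classifiers. Monotone increasing, saturating at 0
#' and 1 for extreme arguments.
#'
#' @param x Numeric vector.
#' @return Numeric vector in (0, 1).
#' @export
#' @examples
#' aps_logi(0)      # 0.5
#' aps_logi(log(3)) # 0.75
aps_logi <- function(x) 1 / (1 + exp(clamp_exp(-x)))

#' Six-marker evolved classifier score
#'
#' The published six-input symbolic classifier. Inputs are the raw serum
#' values `x0` = LDH (u/l), `x1` = CRP (mg/l), `x2` = Na+ (mmol/l),
#' `x3` = Cl- (mmol/l), `x4` = CEA (ng/ml), `x5` = NSE (ng/ml). The score is
#' the sum of the terms
#' `x0`, `-(x4*x5)*log10(x0)`, `exp(apsLogi(x3))`, `x4*apsLogi(x5)`,
#' `x2*apsLogi(apsLogi(1/(apsLogi(x0) + x4)))`, `exp(apsLogi(log10(x3)))`,
#' `x1`, `-x2` and `x5`; each `exp` applies to the single following
#' sigmoid term (the canonical parse; the formula's flat typesetting is
#' ambiguous, so the parse is centralized here). Scores for records with
#' `x0 <= 0` or `x3 <= 0` (outside the log10 domains) are non-finite
#' (`NaN`).
#'
#' @param ldh,crp,na,cl,cea,nse Numeric vectors of raw marker values.
#' @return Numeric score vector; `NaN` marks domain violations.
#' @export
model1_score <- function(ldh, crp, na, cl, cea, nse) {
  x0 <- ldh; x1 <- crp; x2 <- na; x3 <- cl; x4 <- cea; x5 <- nse
  bad <- !is.finite(x0) | !is.finite(x3) | x0 <= 0 | x3 <= 0
  x0 <- ifelse(bad, NA_real_, x0)
  x3 <- ifelse(bad, NA_real_, x3)
  y <- x0 -
    (x4 * x5) * log10(x0) +
    exp(clamp_exp(aps_logi(x3))) +
    x4 * aps_logi(x5) +
    x2 * aps_logi(aps_logi(1 / (aps_logi(x0) + x4))) +
    exp(clamp_exp(aps_logi(log10(x3)))) +
    x1 - x2 + x5
  ifelse(bad, NaN, y)
}

#' Four-marker evolved classifier score
#'
#' The published four-input symbolic classifier, dropping the electrolytes:
#' `x0` = LDH, `x1` = CRP, `x2` = CEA, `x3` = NSE, with
#' `y = exp(x3)*x3*x2 + apsLogi(x0) + x0*x3*(x1 + x2 - 1) - log10(x3)
#'     + x0^2 * (log10(x0) + x2 - x3 + exp(x1*x3))`.
#' Exponent arguments are clamped to +-700, so raw-unit CRP*NSE products
#' stay finite; `x0 <= 0` or `x3 <= 0` gives a non-finite score.
#'
#' @param ldh,crp,cea,nse Numeric vectors of raw marker values.
#' @return Numeric score vector; `NaN` marks domain violations.
#' @export
model2_score <- function(ldh, crp, cea, nse) {
  x0 <- ldh; x1 <- crp; x2 <- cea; x3 <- nse
  bad <- !is.finite(x0) | !is.finite(x3) | x0 <= 0 | x3 <= 0
  x0 <- ifelse(bad, NA_real_, x0)
  x3 <- ifelse(bad, NA_real_, x3)
  y <- exp(clamp_exp(x3)) * x3 * x2 +
    aps_logi(x0) +
    x0 * x3 * (x1 + x2 - 1) -
    log10(x3) +
    x0^2 * (log10(x0) + x2 - x3 + exp(clamp_exp(x1 * x3)))
  ifelse(bad, NaN, y)
}

#' Fit per-marker min-max scaling
#'
#' Learns `(min, max)` per marker on a reference cohort so records can be
#' rescaled to \[0, 1\] before scoring. Scaling is optional and off by
#' default throughout the package; the fit can be persisted with
#' [write_scaling()].
#'
#' @param data Cohort data frame.
#' @param markers Marker columns to fit.
#' @return A `marker_scaling` tibble with columns `marker`, `min`, `max`.
#' @export
fit_marker_scaling <- function(data, markers = marker_names()) {
  if (!all(markers %in% names(data))) {
    param_error("All `markers` must be columns of `data`.")
  }
  out <- purrr::map_dfr(markers, function(m) {
    tibble::tibble(marker = m, min = min(data[[m]], na.rm = TRUE),
                   max = max(data[[m]], na.rm = TRUE))
  })
  if (any(out$max <= out$min)) {
    param_error("Constant marker column: min-max scaling is undefined.")
  }
  structure(out, class = c("marker_scaling", class(out)))
}

#' Apply a fitted min-max scaling
#'
#' @param data Cohort data frame.
#' @param scaling A `marker_scaling` from [fit_marker_scaling()], or `NULL`
#'   for the identity.
#' @return `data` with the scaled marker columns.
#' @export
apply_marker_scaling <- function(data, scaling) {
  if (is.null(scaling)) return(data)
  for (i in seq_len(nrow(scaling))) {
    m <- scaling$marker[i]
    data[[m]] <- (data[[m]] - scaling$min[i]) / (scaling$max[i] - scaling$min[i])
  }
  data
}

#' @rdname fit_marker_scaling
#' @param scaling A `marker_scaling`.
#' @param path JSON path.
#' @export
write_scaling <- function(scaling, path) {
  jsonlite::write_json(as.data.frame(scaling), path, digits = NA)
  invisible(path)
}

#' @rdname fit_marker_scaling
#' @export
read_scaling <- function(path) {
  out <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  structure(out, class = c("marker_scaling", class(out)))
}

published_model_markers <- function(model) {
  switch(as.character(model),
         "1" = marker_names(),
         "2" = c("ldh", "crp", "cea", "nse"),
         param_error("`model` must be 1 or 2."))
}

#' Score a cohort with a published classifier
#'
#' Applies optional per-marker min-max scaling, evaluates the chosen
#' evolved formula on every record, and thresholds: a score equal to or
#' greater than the rounding threshold classifies the record as the
#' positive (patient) class `1`.
#'
#' @param data Cohort data frame with the needed marker columns.
#' @param model `1` (six markers) or `2` (four markers).
#' @param threshold Rounding threshold (default 0.5).
#' @param scaling Optional `marker_scaling`; `NULL` scores raw units.
#' @return A tibble with `subject_id` (if present), `score` and `class`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_sclc = 3, n_nsclc = 0,
#'                                       n_control = 3), seed = 1)
#' score_published(cohort, model = 1)
score_published <- function(data, model = 1, threshold = 0.5,
                            scaling = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold)) {
    param_error("`threshold` must be a single number.")
  }
  markers <- published_model_markers(model)
  missing <- setdiff(markers, names(data))
  if (length(missing) > 0) {
    param_error(sprintf("Missing marker column(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  data <- apply_marker_scaling(data, scaling)
  y <- if (model == 1) {
    model1_score(data$ldh, data$crp, data$na, data$cl, data$cea, data$nse)
  } else {
    model2_score(data$ldh, data$crp, data$cea, data$nse)
  }
  out <- tibble::tibble(score = y,
                        class = as.integer(is.finite(y) & y >= threshold))
  if ("subject_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(subject_id = data$subject_id), out)
  }
  out
}

# Hand-built expression trees of the two published formulas in the engine's
# node representation, used to cross-check the scorers against the engine
# evaluator (same semantics, different code path).
published_model_tree <- function(model, structure) {
  s <- structure
  id <- function(name) match(name, s$symbol_names)
  node <- function(sym, ...) list(sym = id(sym), kids = list(...))
  leaf <- function(term) list(sym = id(term), kids = list())
  cst <- function(v) list(sym = s$const_id, kids = list(), value = v)

  tree <- if (model == 1) {
    x0 <- leaf("ldh"); x1 <- leaf("crp"); x2 <- leaf("na")
    x3 <- leaf("cl"); x4 <- leaf("cea"); x5 <- leaf("nse")
    terms <- list(
      x0,
      node("-", cst(0), node("*", node("*", x4, x5), node("Log", x0))),
      node("Exp", node("Logi", x3)),
      node("*", x4, node("Logi", x5)),
      node("*", x2, node("Logi", node("Logi",
        node("Inv", node("+", node("Logi", x0), x4))))),
      node("Exp", node("Logi", node("Log", x3))),
      x1,
      node("-", cst(0), x2),
      x5
    )
    Reduce(function(a, b) node("+", a, b), terms)
  } else {
    x0 <- leaf("ldh"); x1 <- leaf("crp"); x2 <- leaf("cea"); x3 <- leaf("nse")
    terms <- list(
      node("*", node("*", node("Exp", x3), x3), x2),
      node("Logi", x0),
      node("*", node("*", x0, x3),
           node("-", node("+", x1, x2), cst(1))),
      node("-", cst(0), node("Log", x3)),
      node("*", node("*", x0, x0),
           node("+", node("-", node("+", node("Log", x0), x2), x3),
                node("Exp", node("*", x1, x3))))
    )
    Reduce(function(a, b) node("+", a, b), terms)
  }
  nested_to_tree(tree, s)
}

# Flatten a nested node/leaf representation into the parallel-vector
# gep_tree layout evaluated by eval_tree().
nested_to_tree <- function(nested, structure) {
  sym <- integer(0); child1 <- integer(0); child2 <- integer(0)
  value <- numeric(0); term <- integer(0)
  add <- function(nd) {
    i <- length(sym) + 1L
    sym[i] <<- nd$sym
    child1[i] <<- NA_integer_; child2[i] <<- NA_integer_
    value[i] <<- if (!is.null(nd$value)) nd$value else NA_real_
    term[i] <<- if (nd$sym > structure$n_fun && nd$sym < structure$const_id)
      nd$sym - structure$n_fun else NA_integer_
    if (length(nd$kids) >= 1) child1[i] <<- add(nd$kids[[1]])
    if (length(nd$kids) >= 2) child2[i] <<- add(nd$kids[[2]])
    i
  }
  add(nested)
  structure(list(sym = sym, child1 = child1, child2 = child2, value = value,
                 term = term, n_fun = structure$n_fun,
                 const_id = structure$const_id,
                 symbol_names = structure$symbol_names),
            class = "gep_tree")
}
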