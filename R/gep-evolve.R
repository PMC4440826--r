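#' Evolve a GEP classifier
#'
#' Runs the generational loop: evaluate the accuracy fitness of every
#' chromosome, clone the single best unchanged into the next generation
#' (elitism), select the rest by roulette-wheel sampling proportional to
#' fitness (uniformly when all fitness is zero), and apply the genetic
#' operators. When `generations_without_change` generations pass with no
#' improvement of the best fitness, the run restarts with a fresh population
#' seeded with the best-ever chromosome and one more active gene (complexity
#' increase), up to `number_of_tries` restarts and `max_complexity` active
#' genes. The run stops early when `target_fitness` is reached and always at
#' `max_generations`.
#'
#' @param data A data frame holding the marker columns and a 0/1 label
#'   column (`1` = patient).
#' @param markers Character vector of terminal (marker) column names.
#' @param label Name of the 0/1 label column.
#' @param params A [gep_params()].
#' @param seed Integer seed; defaults to the seed in `params`.
#'
#' @return A `gep_fit` object: the best chromosome, its fitness report, a
#'   per-generation history tibble (`generation`, `try`, `active_genes`,
#'   `best_fitness`), the parameters, terminals and threshold. Supports
#'   [predict()][predict.gep_fit], [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_sclc = 30, n_nsclc = 0,
#'                                       n_control = 30), seed = 1)
#' cohort$case <- as.integer(cohort$group == "SCLC")
#' fit <- gep_evolve(cohort, markers = c("nse", "ldh"), label = "case",
#'                   params = gep_params(population_size = 20,
#'                                       max_generations = 30, seed = 1))
#' glance(fit)
gep_evolve <- function(data, markers = marker_names(), label = "class",
                       params = gep_params(), seed = params$seed) {
  if (!all(markers %in% names(data))) {
    param_error("All `markers` must be columns of `data`.")
  }
  if (!label %in% names(data)) {
    param_error(sprintf("Label column '%s' not found in `data`.", label))
  }
  if (nrow(data) == 0) param_error("Dataset must be non-empty.")
  X <- as.matrix(data[, markers, drop = FALSE])
  labels <- as.integer(data[[label]])
  if (any(!labels %in% c(0L, 1L))) param_error("Labels must be 0/1.")
  if (length(unique(labels)) < 2L) {
    warn("All records share one class; fitness degenerates to the majority rate.")
  }

  s <- gene_structure(params$head_length, markers, gep_function_set(),
                      params$constants_per_gene)
  thr <- params$rounding_threshold
  set.seed(derive_seed(seed, 101L))

  active <- params$initial_complexity
  pop <- replicate(params$population_size,
                   random_chromosome(s, params, active), simplify = FALSE)
  best <- NULL
  best_fit <- -Inf
  try_no <- 1L
  stagnation <- 0L
  hist_gen <- hist_fit <- numeric(0)
  hist_try <- hist_act <- integer(0)

  for (gen in seq_len(params$max_generations)) {
    fits <- vapply(pop, function(ch) {
      fitness_report(ch, X, labels, s, thr)$fitness
    }, numeric(1))
    gen_best <- which.max(fits)  # lowest index wins ties
    if (fits[gen_best] > best_fit) {
      best_fit <- fits[gen_best]
      best <- pop[[gen_best]]
      stagnation <- 0L
    } else {
      stagnation <- stagnation + 1L
    }
    hist_gen <- c(hist_gen, gen); hist_fit <- c(hist_fit, best_fit)
    hist_try <- c(hist_try, try_no); hist_act <- c(hist_act, active)

    if (best_fit >= params$target_fitness) break
    if (stagnation >= params$generations_without_change) {
      if (try_no > params$number_of_tries) break
      # complexity increase: restart around the elite with one more
      # active gene
      try_no <- try_no + 1L
      active <- min(active + 1L, params$max_complexity)
      elite <- best
      elite$active <- active
      pop <- c(list(elite),
               replicate(params$population_size - 1L,
                         random_chromosome(s, params, active),
                         simplify = FALSE))
      stagnation <- 0L
      next
    }

    # selection: elitism + roulette wheel
    elite <- pop[[gen_best]]
    probs <- if (sum(fits) > 0) fits / sum(fits) else
      rep(1 / length(fits), length(fits))
    idx <- sample.int(length(pop), params$population_size - 1L,
                      replace = TRUE, prob = probs)
    offspring <- apply_operators(pop[idx], s, params)
    pop <- c(list(elite), offspring)
  }

  report <- fitness_report(best, X, labels, s, thr)
  structure(
    list(best = best, fitness = report$fitness, confusion = report$confusion,
         history = tibble::tibble(generation = hist_gen, try = hist_try,
                                  active_genes = hist_act,
                                  best_fitness = hist_fit),
         params = params, markers = markers, threshold = thr,
         structure = s, seed = seed),
    class = "gep_fit"
  )
}

#' @export
print.gep_fit <- function(x, ...) {
  cat("<gep_fit> training fitness ", format(x$fitness, digits = 4), " after ",
      nrow(x$history), " generations (", max(x$history$try), " tries, ",
      x$best$active, " active genes)\n", sep = "")
  for (g in seq_len(x$best$active)) {
    cat("  gene ", g, ": ", karva_string(x$best$genes[[g]], x$structure),
        "\n", sep = "")
  }
  invisible(x)
}

#' Predict from a fitted GEP classifier
#'
#' @param object A `gep_fit`.
#' @param newdata Data frame holding the fit's marker columns.
#' @param type `"class"` for 0/1 labels, `"score"` for the raw chromosome
#'   output.
#' @param ... Unused.
#' @return A tibble with columns `score` and `class`.
#' @export
predict.gep_fit <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$markers, drop = FALSE])
  cl <- classify_chromosome(object$best, X, object$structure,
                            object$threshold)
  out <- tibble::tibble(score = cl$score, class = cl$class)
  if (type == "score") out$score else out
}

#' @describeIn gep_evolve Per-generation best-fitness history as a tibble.
#' @param x A `gep_fit`.
#' @param ... Unused.
#' @export
tidy.gep_fit <- function(x, ...) x$history

#' @describeIn gep_evolve One-row summary: final fitness, confusion counts,
#'   generations, tries and active genes.
#' @export
glance.gep_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(fitness = x$fitness, generations = nrow(x$history),
                   tries = max(x$history$try), active_genes = x$best$active),
    x$confusion
  )
}

#' @describeIn gep_evolve Best-fitness trajectory plot; restart boundaries
#'   are drawn as dashed lines.
#' @param object A `gep_fit`.
#' @export
autoplot.gep_fit <- function(object, ...) {
  h <- object$history
  restarts <- h$generation[c(FALSE, diff(h$try) > 0)]
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$generation,
                                       y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "generation", y = "best fitness (accuracy)")
  if (length(restarts) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = restarts, linetype = "dashed",
                                 colour = "grey50")
  }
  p
}
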