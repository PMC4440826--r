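#' Tail length of a GEP gene
#'
#' For a head of length `h` over a function set whose maximum arity is `n`,
#' the tail length `t = h * (n - 1) + 1` guarantees that every head is
#' decodable into a complete expression tree. With the default head of 8 and
#' maximum arity 2 the karva coding region is 8 + 9 = 17 symbols.
#'
#' @param head_length Head length `h`, a positive integer.
#' @param max_arity Maximum arity `n` of the function set, a positive
#'   integer.
#' @return The tail length, an integer.
#' @export
#' @examples
#' tail_length(8, 2)  # 9, so head + tail = 17
tail_length <- function(head_length, max_arity) {
  if (!is.numeric(head_length) || length(head_length) != 1L ||
      is.na(head_length) || head_length < 1 ||
      head_length != round(head_length)) {
    param_error("`head_length` must be a positive integer.")
  }
  if (!is.numeric(max_arity) || length(max_arity) != 1L || is.na(max_arity) ||
      max_arity < 1 || max_arity != round(max_arity)) {
    param_error("`max_arity` must be a positive integer.")
  }
  as.integer(head_length * (max_arity - 1) + 1)
}

#' Default GEP function set
#'
#' Arithmetic plus the unary functions used by the published classifiers:
#' `Exp` (exponential, argument clamped to +-700), `Sqrt` (square root),
#' `Log` (base-10 logarithm), `Logi` (the logistic sigmoid
#' `1 / (1 + exp(-x))`) and `Inv` (reciprocal). All partial functions return
#' a non-finite sentinel outside their domain instead of raising.
#'
#' @return A `gep_function_set`: a list with `names`, `arity`, and the
#'   evaluation semantics.
#' @export
gep_function_set <- function() {
  structure(
    list(names = c("+", "-", "*", "/", "Exp", "Sqrt", "Log", "Logi", "Inv"),
         arity = c(2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L)),
    class = "gep_function_set"
  )
}

#' GEP run parameters
#'
#' All tunable settings of the evolutionary engine. The defaults are the
#' published configuration: 100 chromosomes of 5 genes, head size 8 (gene
#' size 17 with the arity-2 function set), addition as the linking function,
#' mutation rate 0.044, inversion/IS/RIS/gene-transposition and gene
#' recombination at 0.1, one- and two-point recombination at 0.3, ten
#' floating-point random constants per gene in \[-10, 10\], and a complexity
#' schedule that restarts after 200 generations without improvement, up to 3
#' tries, towards a maximum complexity of 5 active genes.
#'
#' `max_generations` caps the total generational budget and
#' `rounding_threshold` is the score cutoff for the positive class; both are
#' configurable because the original tool does not expose their values.
#' `initial_complexity` is the number of active genes before the first
#' restart.
#'
#' @param population_size Number of chromosomes (>= 2).
#' @param genes Genes per chromosome.
#' @param head_length Head size of every gene.
#' @param mutation_rate Per-symbol point-mutation probability.
#' @param inversion_rate,is_transposition_rate,ris_transposition_rate,gene_transposition_rate
#'   Per-chromosome probabilities of the corresponding operator.
#' @param one_point_recomb_rate,two_point_recomb_rate,gene_recomb_rate
#'   Per-pair recombination probabilities.
#' @param constants_per_gene Size of each gene's random-constant pool.
#' @param constant_bounds Length-2 numeric range for random constants.
#' @param generations_without_change Stagnation window triggering a restart.
#' @param number_of_tries Maximum number of stagnation restarts.
#' @param max_complexity Maximum number of active genes.
#' @param initial_complexity Active genes at the start of the run.
#' @param max_generations Total generation cap.
#' @param rounding_threshold Classification cutoff on the chromosome output.
#' @param target_fitness Stop early when best fitness reaches this value.
#' @param seed Default integer seed for [gep_evolve()].
#'
#' @return An object of class `gep_params`.
#' @export
gep_params <- function(population_size = 100, genes = 5, head_length = 8,
                       mutation_rate = 0.044, inversion_rate = 0.1,
                       is_transposition_rate = 0.1,
                       ris_transposition_rate = 0.1,
                       one_point_recomb_rate = 0.3,
                       two_point_recomb_rate = 0.3,
                       gene_recomb_rate = 0.1,
                       gene_transposition_rate = 0.1,
                       constants_per_gene = 10,
                       constant_bounds = c(-10, 10),
                       generations_without_change = 200,
                       number_of_tries = 3,
                       max_complexity = 5,
                       initial_complexity = max(1, max_complexity - number_of_tries),
                       max_generations = 2000,
                       rounding_threshold = 0.5,
                       target_fitness = 1,
                       seed = 1L) {
  p <- list(population_size = as.integer(population_size),
            genes = as.integer(genes), head_length = as.integer(head_length),
            mutation_rate = mutation_rate, inversion_rate = inversion_rate,
            is_transposition_rate = is_transposition_rate,
            ris_transposition_rate = ris_transposition_rate,
            one_point_recomb_rate = one_point_recomb_rate,
            two_point_recomb_rate = two_point_recomb_rate,
            gene_recomb_rate = gene_recomb_rate,
            gene_transposition_rate = gene_transposition_rate,
            constants_per_gene = as.integer(constants_per_gene),
            constant_bounds = as.numeric(constant_bounds),
            generations_without_change = as.integer(generations_without_change),
            number_of_tries = as.integer(number_of_tries),
            max_complexity = as.integer(max_complexity),
            initial_complexity = as.integer(initial_complexity),
            max_generations = as.integer(max_generations),
            rounding_threshold = rounding_threshold,
            target_fitness = target_fitness,
            seed = as.integer(seed))
  rates <- c("mutation_rate", "inversion_rate", "is_transposition_rate",
             "ris_transposition_rate", "one_point_recomb_rate",
             "two_point_recomb_rate", "gene_recomb_rate",
             "gene_transposition_rate")
  for (r in rates) {
    if (!is.numeric(p[[r]]) || p[[r]] < 0 || p[[r]] > 1) {
      param_error(sprintf("`%s` must lie in [0, 1].", r))
    }
  }
  if (p$population_size < 2) param_error("`population_size` must be >= 2.")
  if (p$genes < 1) param_error("`genes` must be >= 1.")
  if (p$head_length < 1) param_error("`head_length` must be >= 1.")
  if (length(p$constant_bounds) != 2 ||
      p$constant_bounds[1] >= p$constant_bounds[2]) {
    param_error("`constant_bounds` must be an ordered length-2 range.")
  }
  if (p$constants_per_gene < 1) param_error("`constants_per_gene` must be >= 1.")
  if (p$max_complexity < 1 || p$max_complexity > p$genes) {
    param_error("`max_complexity` must lie in [1, genes].")
  }
  if (p$initial_complexity < 1 || p$initial_complexity > p$max_complexity) {
    param_error("`initial_complexity` must lie in [1, max_complexity].")
  }
  structure(p, class = "gep_params")
}

#' @export
print.gep_params <- function(x, ...) {
  cat("<gep_params> population", x$population_size, "| genes", x$genes,
      "| head", x$head_length, "| gene size",
      x$head_length + tail_length(x$head_length, 2L), "\n")
  invisible(x)
}

# Static structural description shared by every gene of a run.
gene_structure <- function(head_length, terminals, funset = gep_function_set(),
                           constants_per_gene = 10L) {
  if (length(terminals) == 0) param_error("Terminal set must be non-empty.")
  n_max <- max(funset$arity)
  t_len <- tail_length(head_length, n_max)
  n_fun <- length(funset$names)
  structure(
    list(h = as.integer(head_length), t = t_len, n_max = n_max,
         terminals = terminals, n_fun = n_fun, n_term = length(terminals),
         const_id = n_fun + length(terminals) + 1L,
         n_const = as.integer(constants_per_gene),
         # arity by symbol id: functions, then terminals and the constant
         # reference (arity 0)
         arity = c(funset$arity, rep(0L, length(terminals) + 1L)),
         symbol_names = c(funset$names, terminals, "?"),
         funset = funset),
    class = "gep_gene_structure"
  )
}
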