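# A gene is a fixed-length karva symbol string plus its random-constant
# domain: `symbols` (integer ids, length h + t), `dc` (indices into the
# constant pool, length t), `consts` (the pool itself). Head positions may
# hold functions, terminals or the constant reference "?"; tail positions
# terminals or "?" only.

#' Create a random GEP gene
#'
#' Head symbols are drawn uniformly from functions, terminals and the
#' constant reference; tail symbols from terminals and the constant
#' reference; constants uniformly from `constant_bounds`.
#'
#' @param structure A gene structure (internal; built by [gep_evolve()]).
#' @param params A [gep_params()] object.
#' @return A `gep_gene` list with `symbols`, `dc` and `consts`.
#' @keywords internal
random_gene <- function(structure, params) {
  s <- structure
  head_pool <- seq_len(s$n_fun + s$n_term + 1L)
  tail_pool <- (s$n_fun + 1L):(s$n_fun + s$n_term + 1L)
  structure(
    list(symbols = c(sample(head_pool, s$h, replace = TRUE),
                     sample(tail_pool, s$t, replace = TRUE)),
         dc = sample.int(s$n_const, s$t, replace = TRUE),
         consts = runif(s$n_const, params$constant_bounds[1],
                        params$constant_bounds[2])),
    class = "gep_gene"
  )
}

random_chromosome <- function(structure, params, active) {
  structure(
    list(genes = replicate(params$genes, random_gene(structure, params),
                           simplify = FALSE),
         active = as.integer(active), linking = "+"),
    class = "gep_chromosome"
  )
}

validate_gene <- function(gene, structure) {
  s <- structure
  if (length(gene$symbols) != s$h + s$t) {
    structural_error("Gene symbol string has the wrong length.")
  }
  tail_syms <- gene$symbols[(s$h + 1L):(s$h + s$t)]
  if (any(tail_syms <= s$n_fun)) {
    structural_error("Function symbol in the gene tail.")
  }
  if (any(gene$symbols < 1L | gene$symbols > s$const_id)) {
    structural_error("Unknown symbol id in gene.")
  }
  invisible(gene)
}

#' Decode a karva gene into an expression tree
#'
#' Breadth-first (level-order) decoding: the first symbol is the root and
#' each function node consumes the next arity-many unread symbols as its
#' children. Symbols beyond the open reading frame are ignored. Constant
#' references are resolved against the gene's constant pool in reading
#' order through the Dc domain.
#'
#' @param gene A `gep_gene`.
#' @param structure The gene structure it was built under.
#' @return A `gep_tree`: parallel vectors `sym` (symbol id per node),
#'   `child1`/`child2` (node indices or `NA`), `value` (constant value for
#'   constant nodes), `term` (terminal index for terminal nodes).
#' @keywords internal
decode_gene <- function(gene, structure) {
  s <- structure
  validate_gene(gene, s)
  sym <- gene$symbols
  ar <- s$arity
  total <- 1L
  i <- 1L
  child1 <- child2 <- rep(NA_integer_, s$h + s$t)
  while (i <= total) {
    a <- ar[sym[i]]
    if (a >= 1L) child1[i] <- total + 1L
    if (a >= 2L) child2[i] <- total + 2L
    total <- total + a
    i <- i + 1L
  }
  if (total > s$h + s$t) {
    structural_error("Open reading frame exceeds the gene length.")
  }
  n <- total
  nsym <- sym[seq_len(n)]
  value <- rep(NA_real_, n)
  is_const <- nsym == s$const_id
  if (any(is_const)) {
    value[is_const] <- gene$consts[gene$dc[seq_len(sum(is_const))]]
  }
  term <- rep(NA_integer_, n)
  is_term <- nsym > s$n_fun & nsym < s$const_id
  term[is_term] <- nsym[is_term] - s$n_fun
  structure(list(sym = nsym, child1 = child1[seq_len(n)],
                 child2 = child2[seq_len(n)], value = value, term = term,
                 n_fun = s$n_fun, const_id = s$const_id,
                 symbol_names = s$symbol_names),
            class = "gep_tree")
}

#' @export
format.gep_gene <- function(x, ...) {
  paste(x$symbols, collapse = ".")
}

karva_string <- function(gene, structure) {
  paste(structure$symbol_names[gene$symbols], collapse = " ")
}

#' @export
print.gep_chromosome <- function(x, ...) {
  cat("<gep_chromosome> ", length(x$genes), " genes (", x$active,
      " active), linked by '", x$linking, "'\n", sep = "")
  invisible(x)
}
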