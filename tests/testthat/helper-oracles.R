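# Independent oracles used across the suite. Each reimplements the checked
# operation by a different route than the package: recursive tree
# construction instead of level-order decoding, scalar recursion instead of
# a vectorized reverse sweep, closed forms and brute-force enumeration
# instead of the package's formulas.

oracle_arities <- c("+" = 2, "-" = 2, "*" = 2, "/" = 2, Exp = 1, Sqrt = 1,
                    Log = 1, Logi = 1, Inv = 1)

# Recursive karva decoder: computes the breadth-first levels of the symbol
# string explicitly, then builds the nested tree top-down.
oracle_decode <- function(symbols, values = NULL) {
  ar <- function(s) if (s %in% names(oracle_arities)) oracle_arities[[s]] else 0
  levels <- list(1L)
  pos <- 1L
  repeat {
    cur <- levels[[length(levels)]]
    need <- sum(vapply(symbols[cur], ar, numeric(1)))
    if (need == 0) break
    levels[[length(levels) + 1L]] <- (pos + 1L):(pos + need)
    pos <- pos + need
  }
  build <- function(idx, lvl) {
    a <- ar(symbols[idx])
    val <- if (!is.null(values)) values[idx] else NA_real_
    if (a == 0) return(list(sym = symbols[idx], value = val, kids = list()))
    cur <- levels[[lvl]]
    nxt <- levels[[lvl + 1L]]
    before <- cur[seq_len(match(idx, cur) - 1L)]
    off <- sum(vapply(symbols[before], ar, numeric(1)))
    kids <- lapply(seq_len(a), function(j) build(nxt[off + j], lvl + 1L))
    list(sym = symbols[idx], value = val, kids = kids)
  }
  build(1L, 1L)
}

# Scalar recursive safe evaluator over a named input list.
oracle_eval <- function(node, inputs) {
  s <- node$sym
  if (s == "?") return(node$value)
  if (!s %in% names(oracle_arities)) return(inputs[[s]])
  a <- oracle_eval(node$kids[[1]], inputs)
  b <- if (length(node$kids) > 1) oracle_eval(node$kids[[2]], inputs) else NULL
  cl <- function(x) min(max(x, -700), 700)
  switch(s,
         "+" = a + b, "-" = a - b, "*" = a * b, "/" = a / b,
         Exp = exp(cl(a)),
         Sqrt = if (is.na(a) || a < 0) NaN else sqrt(a),
         Log = suppressWarnings(log10(a)),
         Logi = 1 / (1 + exp(cl(-a))),
         Inv = 1 / a)
}

# Level-order karva encoding of a nested tree, padded to a legal gene.
oracle_encode <- function(tree, head_length, terminals, pad = terminals[1]) {
  syms <- character(0)
  queue <- list(tree)
  while (length(queue) > 0) {
    nd <- queue[[1]]; queue <- queue[-1]
    syms <- c(syms, nd$sym)
    queue <- c(queue, nd$kids)
  }
  t_len <- head_length + 1L
  stopifnot(length(syms) <= head_length + t_len)
  c(syms, rep(pad, head_length + t_len - length(syms)))
}

# All distinct expression trees up to a given depth over a terminal set.
enumerate_trees <- function(depth, terminals) {
  leafs <- lapply(terminals, function(t) list(sym = t, kids = list()))
  if (depth == 1) return(leafs)
  sub <- enumerate_trees(depth - 1, terminals)
  out <- leafs
  for (f in names(oracle_arities)) {
    if (oracle_arities[[f]] == 1) {
      for (k in sub) out <- c(out, list(list(sym = f, kids = list(k))))
    } else {
      for (k1 in sub) for (k2 in sub) {
        out <- c(out, list(list(sym = f, kids = list(k1, k2))))
      }
    }
  }
  out
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  splits <- utils::combn(n, n1)
  us <- apply(splits, 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Exact two-sided mid-p: counts the observed statistic at half weight,
# the standard discreteness adjustment when comparing against an
# uncorrected normal approximation.
oracle_mw_exact_midp <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  lo <- mean(us < u_obs) + 0.5 * mean(us == u_obs)
  hi <- mean(us > u_obs) + 0.5 * mean(us == u_obs)
  min(1, 2 * min(lo, hi))
}

# Independent scalar evaluations of the two published formulas, written
# term by term from their definitions.
oracle_model1 <- function(v) {
  logi <- function(x) 1 / (1 + exp(-x))
  x0 <- v[1]; x1 <- v[2]; x2 <- v[3]; x3 <- v[4]; x4 <- v[5]; x5 <- v[6]
  if (x0 <= 0 || x3 <= 0) return(NaN)
  x0 - (x4 * x5) * log10(x0) + exp(logi(x3)) + x4 * logi(x5) +
    x2 * logi(logi(1 / (logi(x0) + x4))) + exp(logi(log10(x3))) +
    x1 - x2 + x5
}

oracle_model2 <- function(v) {
  logi <- function(x) 1 / (1 + exp(-x))
  cl <- function(x) min(max(x, -700), 700)
  x0 <- v[1]; x1 <- v[2]; x2 <- v[3]; x3 <- v[4]
  if (x0 <= 0 || x3 <= 0) return(NaN)
  exp(cl(x3)) * x3 * x2 + logi(x0) + x0 * x3 * (x1 + x2 - 1) - log10(x3) +
    x0^2 * (log10(x0) + x2 - x3 + exp(cl(x1 * x3)))
}

# A small linearly-separable classification task: the positive class is
# defined by NSE above the clinical cutoff with a safety margin.
make_separable_task <- function(n = 200, seed = 99) {
  set.seed(seed)
  half <- n %/% 2
  tibble::tibble(
    ldh = runif(n, 50, 400), crp = runif(n, 0.1, 20),
    na = runif(n, 130, 147), cl = runif(n, 95, 111),
    cea = runif(n, 0.2, 15),
    nse = c(runif(half, 18.5, 60), runif(n - half, 2, 15.5)),
    class = rep(c(1L, 0L), c(half, n - half))
  )
}

small_cohort <- function(n_per = 25, seed = 5) {
  generate_cohort(cohort_spec(n_sclc = n_per, n_nsclc = n_per,
                              n_control = n_per), seed = seed)
}
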