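engine_structure <- function(head_length = 8, terminals = c("a", "b"),
                             n_const = 10) {
  gepdx:::gene_structure(head_length, terminals, gep_function_set(), n_const)
}

gene_from_names <- function(names, structure, dc = NULL, consts = NULL) {
  ids <- match(names, structure$symbol_names)
  stopifnot(!anyNA(ids))
  if (is.null(dc)) dc <- rep(1L, structure$t)
  if (is.null(consts)) consts <- rep(0, structure$n_const)
  structure(list(symbols = as.integer(ids), dc = dc, consts = consts),
            class = "gep_gene")
}

test_that("tail length follows t = h(n - 1) + 1", {
  expect_identical(tail_length(8, 2), 9L)
  expect_identical(8L + tail_length(8, 2), 17L)
  expect_identical(tail_length(1, 1), 1L)
  expect_identical(tail_length(10, 3), 21L)
  expect_error(tail_length(0, 2), class = "gepdx_parameter_error")
  expect_error(tail_length(8, 0), class = "gepdx_parameter_error")
})

test_that("random genes satisfy the head/tail invariants deterministically", {
  s <- engine_structure()
  p <- gep_params()
  set.seed(1); g1 <- gepdx:::random_gene(s, p)
  set.seed(1); g2 <- gepdx:::random_gene(s, p)
  expect_identical(g1, g2)
  expect_silent(gepdx:::validate_gene(g1, s))
  expect_error(gepdx:::gene_structure(8, character(0)),
               class = "gepdx_parameter_error")

  # uniform constants stay inside their bounds with the right mean
  set.seed(7)
  draws <- replicate(1000, gepdx:::random_gene(s, p)$consts)
  expect_true(all(draws >= -10 & draws <= 10))
  expect_lt(abs(mean(draws)), 0.5)
})

test_that("karva decoding is level-order with an open reading frame", {
  s <- engine_structure(head_length = 4)  # t = 5, gene length 9
  # "* + c a b ..." decodes to (a + b) * c with c a constant leaf
  g <- gene_from_names(c("*", "+", "?", "a", "b", "a", "a", "a", "a"), s,
                       dc = c(3L, rep(1L, 4)),
                       consts = c(0, 0, 2.5, rep(0, 7)))
  tree <- gepdx:::decode_gene(g, s)
  expect_length(tree$sym, 5)  # trailing symbols ignored
  X <- cbind(a = c(2, -1), b = c(3, 4))
  expect_equal(gepdx:::eval_tree(tree, X), c((2 + 3) * 2.5, (-1 + 4) * 2.5))

  # terminal root: single-node reading frame
  g2 <- gene_from_names(c("a", "+", "b", "a", "b", "a", "a", "a", "a"), s)
  tree2 <- gepdx:::decode_gene(g2, s)
  expect_length(tree2$sym, 1)
  expect_equal(gepdx:::eval_tree(tree2, X), c(2, -1))

  # a function symbol in the tail is structurally illegal
  bad <- gene_from_names(c("+", "a", "b", "a", "+", "a", "a", "a", "a"), s)
  expect_error(gepdx:::decode_gene(bad, s), class = "gepdx_structural_error")
})

test_that("safe evaluation returns non-finite sentinels outside domains", {
  s <- engine_structure(head_length = 2)  # t = 3
  X <- cbind(a = c(-1, 0, 4), b = c(0, 0, 2))
  ev <- function(names) {
    gepdx:::eval_tree(gepdx:::decode_gene(gene_from_names(names, s), s), X)
  }
  expect_equal(ev(c("+", "a", "b", "a", "a")), c(-1, 0, 6))
  log_res <- ev(c("Log", "a", "b", "a", "a"))
  expect_false(any(is.finite(log_res[1:2])))  # log10 of -1 and of 0
  expect_equal(log_res[3], log10(4))
  inv_res <- ev(c("Inv", "b", "b", "a", "a"))
  expect_false(is.finite(inv_res[1]))
  sqrt_res <- ev(c("Sqrt", "a", "b", "a", "a"))
  expect_true(is.nan(sqrt_res[1]))
  div_res <- ev(c("/", "a", "b", "a", "a"))
  expect_false(any(is.finite(div_res[1:2])))  # -1/0 and 0/0
})

test_that("decoding and evaluation agree with the recursive oracle", {
  # exhaustive over every tree of depth <= 3 on a two-terminal alphabet
  s <- engine_structure(head_length = 7)
  trees <- enumerate_trees(3, c("a", "b"))
  inputs <- list(a = 0.7, b = -1.3)
  X <- cbind(a = inputs$a, b = inputs$b)
  for (tr in trees) {
    syms <- oracle_encode(tr, 7, c("a", "b"))
    g <- gene_from_names(syms, s)
    got <- gepdx:::eval_tree(gepdx:::decode_gene(g, s), X)
    want <- oracle_eval(oracle_decode(syms), inputs)
    if (is.finite(want)) {
      expect_equal(got, want, tolerance = 1e-12)
    } else {
      expect_false(is.finite(got))
    }
  }
})

test_that("random deep genes evaluate identically to the oracle", {
  s <- engine_structure(head_length = 8)
  p <- gep_params()
  set.seed(42)
  for (k in seq_len(1000)) {
    g <- gepdx:::random_gene(s, p)
    names <- s$symbol_names[g$symbols]
    values <- rep(NA_real_, length(names))
    qpos <- which(names == "?")
    values[qpos] <- g$consts[g$dc[seq_along(qpos)]]
    inputs <- list(a = runif(1, -5, 5), b = runif(1, -5, 5))
    X <- cbind(a = inputs$a, b = inputs$b)
    got <- gepdx:::eval_tree(gepdx:::decode_gene(g, s), X)
    want <- oracle_eval(oracle_decode(names, values), inputs)
    if (is.finite(want) && is.finite(got)) {
      expect_equal(got, want, tolerance = 1e-10)
    } else {
      expect_identical(is.finite(got), is.finite(want))
    }
  }
})

test_that("classification thresholds at y >= threshold and flags invalids", {
  s <- engine_structure(head_length = 2, terminals = c("a", "b"))
  chrom <- structure(list(
    genes = list(gene_from_names(c("a", "a", "b", "a", "a"), s)),
    active = 1L, linking = "+"), class = "gep_chromosome")
  X <- cbind(a = c(0.5, 0.49, -5), b = 0)
  out <- gepdx:::classify_chromosome(chrom, X, s, threshold = 0.5)
  expect_identical(out$class, c(1L, 0L, 0L))  # y == threshold is positive

  # monotone in y for a fixed threshold
  ord <- order(out$score)
  expect_true(all(diff(out$class[ord]) >= 0))

  # non-finite output classifies 0 and is flagged
  chrom_inv <- structure(list(
    genes = list(gene_from_names(c("Inv", "b", "b", "a", "a"), s)),
    active = 1L, linking = "+"), class = "gep_chromosome")
  out2 <- gepdx:::classify_chromosome(chrom_inv, cbind(a = 1, b = 0), s, 0.5)
  expect_identical(out2$class, 0L)
  expect_true(out2$invalid)
})

test_that("fitness is the classification accuracy with an invalidity penalty", {
  s <- engine_structure(head_length = 2, terminals = c("a", "b"))
  chrom <- structure(list(
    genes = list(gene_from_names(c("a", "a", "b", "a", "a"), s)),
    active = 1L, linking = "+"), class = "gep_chromosome")
  # a = score; labels chosen to give the published worked example counts
  n <- c(tp = 106, fn = 9, tn = 119, fp = 6)
  X <- cbind(a = c(rep(1, n["tp"]), rep(0, n["fn"]),
                   rep(0, n["tn"]), rep(1, n["fp"])), b = 0)
  labels <- c(rep(1, n["tp"] + n["fn"]), rep(0, n["tn"] + n["fp"]))
  rep <- gepdx:::fitness_report(chrom, X, labels, s, 0.5)
  expect_equal(rep$fitness, 0.9375)
  expect_equal(unlist(rep$confusion), c(tp = 106, fn = 9, tn = 119, fp = 6))

  # any invalid record zeroes the fitness
  chrom_inv <- structure(list(
    genes = list(gene_from_names(c("Inv", "b", "b", "a", "a"), s)),
    active = 1L, linking = "+"), class = "gep_chromosome")
  expect_equal(gepdx:::fitness_report(chrom_inv, cbind(a = 1, b = 0), 1L,
                                      s, 0.5)$fitness, 0)
  expect_error(gepdx:::fitness_report(chrom, X[0, , drop = FALSE],
                                      integer(0), s, 0.5),
               class = "gepdx_parameter_error")
})

test_that("genetic operators preserve gene invariants and rates of zero are the identity", {
  s <- engine_structure()
  p0 <- gep_params(mutation_rate = 0, inversion_rate = 0,
                   is_transposition_rate = 0, ris_transposition_rate = 0,
                   one_point_recomb_rate = 0, two_point_recomb_rate = 0,
                   gene_recomb_rate = 0, gene_transposition_rate = 0)
  set.seed(3)
  pop <- replicate(6, gepdx:::random_chromosome(s, p0, 2L), simplify = FALSE)
  expect_identical(gepdx:::apply_operators(pop, s, p0), pop)

  # structural fuzz at the published rates
  p <- gep_params()
  set.seed(4)
  for (i in seq_len(50)) {
    pop <- gepdx:::apply_operators(pop, s, p)
    for (ch in pop) {
      for (g in ch$genes) expect_silent(gepdx:::validate_gene(g, s))
    }
  }
})

test_that("point mutation at rate 1 always changes a single-symbol head", {
  # one head slot, two terminals and the constant ref: resampling uniformly
  # cannot be the identity more often than chance; over many trials every
  # draw lands in the symbol pool and the head stays legal
  s <- engine_structure(head_length = 1, terminals = c("a", "b"))
  p <- gep_params(head_length = 1, mutation_rate = 1)
  set.seed(9)
  roots <- replicate(200, {
    g <- gepdx:::random_gene(s, p)
    gepdx:::mutate_gene(g, s, p)$symbols[1]
  })
  pool <- seq_len(s$n_fun + s$n_term + 1L)
  expect_true(all(roots %in% pool))
  expect_gt(length(unique(roots)), 5)  # the root really is resampled
})

test_that("evolution is elitist, deterministic and recovers a separable rule", {
  task <- make_separable_task(120, seed = 1)
  p <- gep_params(population_size = 30, max_generations = 60, seed = 5)
  fit <- gep_evolve(task, label = "class", params = p)
  expect_true(all(diff(fit$history$best_fitness) >= 0))
  expect_gte(fit$fitness, 0.9)

  fit2 <- gep_evolve(task, label = "class", params = p)
  expect_identical(fit$best, fit2$best)
  expect_identical(fit$history, fit2$history)

  one_class <- dplyr::mutate(task, class = 1L)
  expect_warning(
    gep_evolve(one_class, label = "class",
               params = gep_params(population_size = 10, max_generations = 3)),
    "majority"
  )
})

test_that("fitted models round-trip bit-exactly through JSON", {
  task <- make_separable_task(60, seed = 2)
  fit <- gep_evolve(task, label = "class",
                    params = gep_params(population_size = 12,
                                        max_generations = 10, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_gep_model(fit, path)
  back <- read_gep_model(path)
  expect_identical(back$best$genes, fit$best$genes)
  expect_identical(back$markers, fit$markers)
  expect_identical(predict(back, task), predict(fit, task))
})

test_that("tidy, glance and autoplot summarise a fit", {
  task <- make_separable_task(60, seed = 3)
  fit <- gep_evolve(task, label = "class",
                    params = gep_params(population_size = 12,
                                        max_generations = 8, seed = 3))
  td <- tidy(fit)
  expect_identical(names(td), c("generation", "try", "active_genes",
                                "best_fitness"))
  gl <- glance(fit)
  expect_equal(gl$fitness, fit$fitness)
  expect_s3_class(autoplot(fit), "ggplot")
})
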