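# The seven genetic operators. Mutation acts per symbol at its configured
# rate; inversion and the three transpositions act per chromosome; the three
# recombinations act on random pairs. Every operator preserves the head/tail
# symbol invariants by construction: insertions happen only in the head
# (truncated back to length h) and recombination swaps position-aligned
# blocks between structurally identical chromosomes.

mutate_gene <- function(gene, structure, params) {
  s <- structure
  rate <- params$mutation_rate
  if (rate <= 0) return(gene)
  head_pool <- seq_len(s$const_id)
  tail_pool <- (s$n_fun + 1L):s$const_id
  hit <- which(runif(s$h + s$t) < rate)
  for (i in hit) {
    gene$symbols[i] <- if (i <= s$h) sample(head_pool, 1L) else
      sample(tail_pool, 1L)
  }
  dc_hit <- which(runif(s$t) < rate)
  if (length(dc_hit) > 0) {
    gene$dc[dc_hit] <- sample.int(s$n_const, length(dc_hit), replace = TRUE)
  }
  c_hit <- which(runif(s$n_const) < rate)
  if (length(c_hit) > 0) {
    gene$consts[c_hit] <- runif(length(c_hit), params$constant_bounds[1],
                                params$constant_bounds[2])
  }
  gene
}

op_mutation <- function(chrom, structure, params) {
  chrom$genes <- lapply(chrom$genes, mutate_gene, structure = structure,
                        params = params)
  chrom
}

op_inversion <- function(chrom, structure, params) {
  if (runif(1) >= params$inversion_rate || structure$h < 2) return(chrom)
  g <- sample.int(length(chrom$genes), 1L)
  pts <- sort(sample.int(structure$h, 2L))
  idx <- pts[1]:pts[2]
  chrom$genes[[g]]$symbols[idx] <- rev(chrom$genes[[g]]$symbols[idx])
  chrom
}

# Insertion-sequence transposition: a short segment copied from anywhere in
# a source gene into a non-root head position of a target gene; the head is
# truncated back to length h.
op_is_transposition <- function(chrom, structure, params) {
  if (runif(1) >= params$is_transposition_rate || structure$h < 2) return(chrom)
  s <- structure
  src <- sample.int(length(chrom$genes), 1L)
  dst <- sample.int(length(chrom$genes), 1L)
  len <- sample.int(min(3L, s$h - 1L), 1L)
  start <- sample.int(s$h + s$t - len + 1L, 1L)
  seg <- chrom$genes[[src]]$symbols[start:(start + len - 1L)]
  pos <- sample(2:s$h, 1L)
  head_sym <- chrom$genes[[dst]]$symbols[seq_len(s$h)]
  new_head <- append(head_sym, seg, after = pos - 1L)[seq_len(s$h)]
  chrom$genes[[dst]]$symbols[seq_len(s$h)] <- new_head
  chrom
}

# Root-insertion-sequence transposition: a segment starting at a function
# symbol in the head becomes the new gene root.
op_ris_transposition <- function(chrom, structure, params) {
  if (runif(1) >= params$ris_transposition_rate) return(chrom)
  s <- structure
  g <- sample.int(length(chrom$genes), 1L)
  head_sym <- chrom$genes[[g]]$symbols[seq_len(s$h)]
  fun_pos <- which(head_sym <= s$n_fun)
  if (length(fun_pos) == 0) return(chrom)
  start <- if (length(fun_pos) == 1L) fun_pos else sample(fun_pos, 1L)
  len <- sample.int(min(3L, s$h - start + 1L), 1L)
  seg <- head_sym[start:(start + len - 1L)]
  new_head <- c(seg, head_sym)[seq_len(s$h)]
  chrom$genes[[g]]$symbols[seq_len(s$h)] <- new_head
  chrom
}

# Gene transposition: a non-first gene moves to the front (its constants
# travel with it). Under an additive linking function the phenotype is
# unchanged, but the genome layout seen by recombination shuffles.
op_gene_transposition <- function(chrom, structure, params) {
  ng <- length(chrom$genes)
  if (ng < 2 || runif(1) >= params$gene_transposition_rate) return(chrom)
  g <- sample(2:ng, 1L)
  chrom$genes <- c(chrom$genes[g], chrom$genes[-g])
  chrom
}

# Flatten a chromosome into one integer vector of per-gene
# [symbols, dc-indices] blocks; constants are exchanged at gene granularity
# (a split gene keeps the constants of the parent providing its tail end).
flatten_chrom <- function(chrom) {
  unlist(lapply(chrom$genes, function(g) c(g$symbols, g$dc)))
}

unflatten_chrom <- function(chrom, flat, const_src, structure) {
  s <- structure
  block <- s$h + 2L * s$t
  for (g in seq_along(chrom$genes)) {
    off <- (g - 1L) * block
    chrom$genes[[g]]$symbols <- flat[(off + 1L):(off + s$h + s$t)]
    chrom$genes[[g]]$dc <- flat[(off + s$h + s$t + 1L):(off + block)]
    chrom$genes[[g]]$consts <- const_src[[g]]$consts
  }
  chrom
}

recombine <- function(c1, c2, structure, n_points) {
  v1 <- flatten_chrom(c1); v2 <- flatten_chrom(c2)
  L <- length(v1)
  s <- structure
  block <- s$h + 2L * s$t
  if (n_points == 1L) {
    p <- sample.int(L - 1L, 1L)
    cut <- c(rep(FALSE, p), rep(TRUE, L - p))
  } else {
    pts <- sort(sample.int(L - 1L, 2L))
    cut <- seq_len(L) > pts[1] & seq_len(L) <= pts[2]
  }
  w1 <- ifelse(cut, v2, v1); w2 <- ifelse(cut, v1, v2)
  # constants follow whichever parent contributes the gene's Dc tail
  gene_side <- function(base, other) {
    lapply(seq_along(base$genes), function(g) {
      if (cut[g * block]) other$genes[[g]] else base$genes[[g]]
    })
  }
  o1 <- unflatten_chrom(c1, w1, gene_side(c1, c2), s)
  o2 <- unflatten_chrom(c2, w2, gene_side(c2, c1), s)
  list(o1, o2)
}

recombine_genes <- function(c1, c2) {
  g <- sample.int(length(c1$genes), 1L)
  tmp <- c1$genes[[g]]
  c1$genes[[g]] <- c2$genes[[g]]
  c2$genes[[g]] <- tmp
  list(c1, c2)
}

#' Apply the GEP genetic operators to a population
#'
#' Point mutation, inversion, IS/RIS/gene transposition and one-point,
#' two-point and whole-gene recombination, each at its configured rate. An
#' odd final survivor simply passes through the pairwise recombination
#' stage unchanged.
#'
#' @param population List of `gep_chromosome`s.
#' @param structure The shared gene structure.
#' @param params A [gep_params()].
#' @return The modified population (same size).
#' @keywords internal
apply_operators <- function(population, structure, params) {
  population <- lapply(population, function(ch) {
    ch <- op_mutation(ch, structure, params)
    ch <- op_inversion(ch, structure, params)
    ch <- op_is_transposition(ch, structure, params)
    ch <- op_ris_transposition(ch, structure, params)
    op_gene_transposition(ch, structure, params)
  })
  n <- length(population)
  if (n >= 2) {
    ord <- sample.int(n)
    for (k in seq_len(n %/% 2L)) {
      i <- ord[2L * k - 1L]; j <- ord[2L * k]
      pair <- list(population[[i]], population[[j]])
      if (runif(1) < params$one_point_recomb_rate) {
        pair <- recombine(pair[[1]], pair[[2]], structure, 1L)
      }
      if (runif(1) < params$two_point_recomb_rate) {
        pair <- recombine(pair[[1]], pair[[2]], structure, 2L)
      }
      if (runif(1) < params$gene_recomb_rate) {
        pair <- recombine_genes(pair[[1]], pair[[2]])
      }
      population[[i]] <- pair[[1]]; population[[j]] <- pair[[2]]
    }
  }
  population
}
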