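## Random fitness landscapes of the three kinds used in the study:
## DAG-representable (single peak), local-maxima (pruned fitness graph),
## and Rough Mount Fuji.

#' Create a DAG of restrictions (poset) over genes
#'
#' An edge `i -> j` means a mutation in gene `i` must occur before a mutation
#' in gene `j`; multiple parents are conjunctive (AND). Genes without parents
#' depend only on the implicit Root.
#'
#' @param n_genes number of genes K.
#' @param edges two-column integer matrix `(parent, child)`; may have 0 rows.
#' @param labels gene labels; defaults to `G1..GK`.
#' @return an object of class `cpm_poset`.
#' @export
new_poset <- function(n_genes, edges = matrix(integer(0), ncol = 2),
                      labels = default_labels(n_genes)) {
  n_genes <- check_n_genes(n_genes)
  edges <- matrix(as.integer(edges), ncol = 2)
  colnames(edges) <- c("parent", "child")
  if (nrow(edges)) {
    if (any(edges < 1L | edges > n_genes)) stop("edge endpoints out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-edges not allowed")
    if (!is_acyclic(n_genes, edges)) stop("edges must form a DAG")
    edges <- edges[!duplicated(edges), , drop = FALSE]
  }
  structure(list(n_genes = n_genes, edges = edges, labels = labels),
            class = "cpm_poset")
}

is_acyclic <- function(n_genes, edges) {
  ## Kahn's algorithm on the gene graph
  indeg <- tabulate(edges[, 2], n_genes)
  active <- rep(TRUE, n_genes)
  repeat {
    src <- which(active & indeg == 0L)
    if (!length(src)) break
    active[src] <- FALSE
    out <- edges[edges[, 1] %in% src & active[edges[, 2]], 2]
    if (length(out)) indeg <- indeg - tabulate(out, n_genes)
  }
  !any(active)
}

#' Generate a random DAG of restrictions
#'
#' Draws a uniform random topological order of the genes and includes each
#' forward gene-to-gene edge independently with probability `density`.
#'
#' @param n_genes number of genes.
#' @param density probability of each forward edge, in \[0, 1\].
#' @param labels gene labels.
#' @return a `cpm_poset`.
#' @export
generate_random_dag <- function(n_genes, density = 0.3,
                                labels = default_labels(n_genes)) {
  n_genes <- check_n_genes(n_genes)
  stopifnot(density >= 0, density <= 1)
  ord <- sample.int(n_genes)
  edges <- matrix(integer(0), ncol = 2)
  if (n_genes > 1L && density > 0) {
    pairs <- which(upper.tri(diag(n_genes)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < density
    edges <- cbind(ord[pairs[keep, 1]], ord[pairs[keep, 2]])
  }
  new_poset(n_genes, edges, labels)
}

#' Bitmask of direct parents for each gene
#' @keywords internal
poset_parent_masks <- function(poset) {
  pm <- integer(poset$n_genes)
  e <- poset$edges
  for (r in seq_len(nrow(e)))
    pm[e[r, 2]] <- bitwOr(pm[e[r, 2]], bitwShiftL(1L, e[r, 1] - 1L))
  pm
}

## genotypes (bitmasks) compatible with the AND restrictions
compatible_masks <- function(parent_masks, n_genes) {
  all_g <- 0:(2L^n_genes - 1L)
  ok <- rep(TRUE, length(all_g))
  for (j in seq_len(n_genes)) {
    bit <- bitwShiftL(1L, j - 1L)
    has_j <- bitwAnd(all_g, bit) > 0L
    ok <- ok & (!has_j | bitwAnd(all_g, parent_masks[j]) == parent_masks[j])
  }
  all_g[ok]
}

#' Fitness graph of a DAG of restrictions
#'
#' Nodes are the genotypes whose mutated genes all have their DAG parents
#' mutated; edges connect every pair of nodes differing by exactly one added
#' mutation.
#'
#' @param dag a `cpm_poset`.
#' @return an object of class `fitness_graph` with fields `n_genes`, `labels`,
#'   `nodes` (genotype bitmasks, sorted by number of mutations), `edges`
#'   (two-column matrix of bitmasks, from -> to) and `pruned` flag.
#' @export
fitness_graph_from_dag <- function(dag) {
  stopifnot(inherits(dag, "cpm_poset"))
  K <- dag$n_genes
  nodes <- compatible_masks(poset_parent_masks(dag), K)
  nodes <- nodes[order(popcount(nodes), nodes)]
  in_set <- logical(2L^K)
  in_set[nodes + 1L] <- TRUE
  from <- integer(0); to <- integer(0)
  for (j in seq_len(K)) {
    bit <- bitwShiftL(1L, j - 1L)
    cand <- nodes[bitwAnd(nodes, bit) == 0L]
    tgt <- bitwOr(cand, bit)
    keep <- in_set[tgt + 1L]
    from <- c(from, cand[keep]); to <- c(to, tgt[keep])
  }
  structure(list(n_genes = K, labels = dag$labels, nodes = nodes,
                 edges = cbind(from = from, to = to), pruned = FALSE,
                 dag = dag),
            class = "fitness_graph")
}

#' Assign birth rates along a fitness graph
#'
#' Iterative procedure: the wild type gets birth rate 1; every other node gets
#' the maximum rate among its in-neighbors times an independent
#' `U(lo, hi)` multiplier, so rates increase strictly along every edge
#' (average multiplicative fitness increase `(lo+hi)/2 - 1`). Genotypes not in
#' the graph get rate exactly 0.
#'
#' @param fgraph a `fitness_graph`.
#' @param lo,hi bounds of the uniform multiplier (defaults 1.01 and 1.19).
#' @return an object of class `fitness_landscape`.
#' @export
assign_birth_rates <- function(fgraph, lo = 1.01, hi = 1.19) {
  stopifnot(inherits(fgraph, "fitness_graph"), 1 < lo, lo < hi)
  K <- fgraph$n_genes
  rate <- numeric(2L^K)
  rate[1L] <- 1
  nodes <- fgraph$nodes[order(popcount(fgraph$nodes), fgraph$nodes)]
  for (g in nodes[nodes != 0L]) {
    parents <- fgraph$edges[fgraph$edges[, 2] == g, 1]
    if (!length(parents))
      stop("node ", geno_string(g, K), " unreachable from wild type")
    rate[g + 1L] <- max(rate[parents + 1L]) * stats::runif(1, lo, hi)
  }
  structure(list(n_genes = K, labels = fgraph$labels, birth_rate = rate,
                 kind = if (fgraph$pruned) "local_maxima" else "representable",
                 graph = fgraph),
            class = "fitness_landscape")
}

#' Remove fitness-graph edges to create local fitness maxima
#'
#' Repeats `n_tries` independent prunings and keeps the one that introduced
#' the largest number of local maxima (out-degree-0 nodes). Each pruning
#' shuffles the edges and removes them one at a time, keeping a removal only
#' if every node remains reachable from the wild type, until
#' `removal_fraction` of the edges have been processed. Nodes (accessible
#' genotypes) are never removed.
#'
#' @param fgraph a `fitness_graph`.
#' @param removal_fraction fraction of edges processed for removal, in \[0, 1).
#' @param n_tries number of independent prunings (default 50).
#' @return a `fitness_graph` with `pruned = TRUE`.
#' @export
prune_to_local_maxima <- function(fgraph, removal_fraction = 0.5,
                                  n_tries = 50L) {
  stopifnot(inherits(fgraph, "fitness_graph"),
            removal_fraction >= 0, removal_fraction < 1)
  if (removal_fraction == 0 || nrow(fgraph$edges) == 0L) return(fgraph)
  fi <- fgraph$edges[, 1]; ti <- fgraph$edges[, 2]
  nE <- length(fi)
  n_nodes <- length(fgraph$nodes)
  target <- floor(removal_fraction * nE)
  all_reachable <- function(removed) {
    reached <- 0L
    repeat {
      new <- setdiff(ti[!removed & (fi %in% reached)], reached)
      if (!length(new)) break
      reached <- c(reached, new)
    }
    length(reached) == n_nodes
  }
  best_removed <- rep(FALSE, nE)
  best_sinks <- sum(!(fgraph$nodes %in% fi))
  for (try in seq_len(n_tries)) {
    removed <- rep(FALSE, nE)
    for (e in sample.int(nE)[seq_len(target)]) {
      removed[e] <- TRUE
      if (!all_reachable(removed)) removed[e] <- FALSE
    }
    sinks <- sum(!(fgraph$nodes %in% fi[!removed]))
    if (sinks > best_sinks) {
      best_sinks <- sinks
      best_removed <- removed
    }
  }
  out <- fgraph
  out$edges <- fgraph$edges[!best_removed, , drop = FALSE]
  out$pruned <- TRUE
  out
}

#' Rough Mount Fuji fitness landscape
#'
#' Log birth rate is `-slope_c * d(g, reference) + eps_g` with
#' `eps_g ~ N(0, hoc_sd^2)` iid (House of Cards component), `d` the Hamming
#' distance to a reference genotype chosen uniformly at random; the draw is
#' repeated until the reference is the unique global maximum (when
#' `slope_c > 0`; for a pure House of Cards landscape the reference is
#' relabelled to the argmax). Rates are rescaled so the wild type has rate 1.
#'
#' @param n_genes number of genes.
#' @param slope_c decrease in log birth rate per unit Hamming distance from
#'   the reference genotype (>= 0).
#' @param hoc_sd standard deviation of the random component (>= 0).
#' @return a `fitness_landscape` of kind `"rmf"`.
#' @export
rmf_landscape <- function(n_genes, slope_c = 0.05, hoc_sd = 0.03) {
  n_genes <- check_n_genes(n_genes)
  stopifnot(slope_c >= 0, hoc_sd >= 0, slope_c + hoc_sd > 0)
  all_g <- 0:(2L^n_genes - 1L)
  reference <- sample(all_g, 1L)
  d <- popcount(bitwXor(all_g, reference))
  for (attempt in seq_len(10000L)) {
    logr <- -slope_c * d + stats::rnorm(length(all_g), 0, hoc_sd)
    if (slope_c == 0) {
      reference <- all_g[which.max(logr)]
      d <- popcount(bitwXor(all_g, reference))
      break
    }
    mx <- which.max(logr)
    if (all_g[mx] == reference && sum(logr == logr[mx]) == 1L) break
  }
  rate <- exp(logr - logr[1L])  # wild type = 1
  structure(list(n_genes = n_genes, labels = default_labels(n_genes),
                 birth_rate = rate, kind = "rmf",
                 provenance = list(reference = reference, slope_c = slope_c,
                                   hoc_sd = hoc_sd)),
            class = "fitness_landscape")
}

## Local maxima of a landscape. For DAG-derived kinds these are the
## fitness-graph sinks. For RMF two neighborhoods are meaningful:
## "hamming" (all K single-mutation neighbors, the classical definition
## used for landscape statistics) and "forward" (only neighbors adding a
## mutation; these are the states at which the no-back-mutation dynamics
## can stop, used as the fixation targets of the simulator — every
## classical maximum is also a forward maximum).
landscape_local_maxima <- function(landscape,
                                   neighborhood = c("hamming", "forward")) {
  neighborhood <- match.arg(neighborhood)
  K <- landscape$n_genes
  if (landscape$kind == "rmf") {
    all_g <- 0:(2L^K - 1L)
    rate <- landscape$birth_rate
    is_max <- rep(TRUE, length(all_g))
    for (j in seq_len(K)) {
      bit <- bitwShiftL(1L, j - 1L)
      nb <- bitwXor(all_g, bit)
      consider <- if (neighborhood == "hamming") rep(TRUE, length(all_g))
                  else bitwAnd(all_g, bit) == 0L
      is_max <- is_max & (!consider | rate[nb + 1L] <= rate[all_g + 1L])
    }
    all_g[is_max]
  } else {
    g <- landscape$graph
    g$nodes[!(g$nodes %in% g$edges[, 1])]
  }
}

## Uphill fitness graph of an RMF landscape (edges that increase fitness)
rmf_fitness_graph <- function(landscape) {
  K <- landscape$n_genes
  all_g <- 0:(2L^K - 1L)
  rate <- landscape$birth_rate
  from <- integer(0); to <- integer(0)
  for (j in seq_len(K)) {
    bit <- bitwShiftL(1L, j - 1L)
    cand <- all_g[bitwAnd(all_g, bit) == 0L]
    up <- bitwOr(cand, bit)
    keep <- rate[up + 1L] > rate[cand + 1L]
    from <- c(from, cand[keep]); to <- c(to, up[keep])
  }
  ## accessible = reachable from wild type along uphill edges
  reached <- 0L
  repeat {
    new <- setdiff(to[from %in% reached], reached)
    if (!length(new)) break
    reached <- c(reached, new)
  }
  keep <- (from %in% reached)
  structure(list(n_genes = K, labels = landscape$labels,
                 nodes = sort(reached),
                 edges = cbind(from = from[keep], to = to[keep]),
                 pruned = FALSE),
            class = "fitness_graph")
}

#' Summary statistics of a fitness landscape
#'
#' A local maximum is a genotype with positive birth rate and no allowed
#' one-mutation neighbor of higher rate (allowed transitions: fitness-graph
#' edges for DAG-derived landscapes; any single added mutation for RMF).
#'
#' @param landscape a `fitness_landscape`.
#' @return list with `n_accessible`, `n_local_maxima` and
#'   `max_genotype_sizes` (numbers of mutations of the local maxima).
#' @export
landscape_stats <- function(landscape) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  maxima <- landscape_local_maxima(landscape)
  n_acc <- if (landscape$kind == "rmf")
    length(rmf_fitness_graph(landscape)$nodes)
  else length(landscape$graph$nodes)
  list(n_accessible = n_acc,
       n_local_maxima = length(maxima),
       max_genotype_sizes = popcount(maxima))
}

#' Generate a random fitness landscape of a given kind
#'
#' Convenience wrapper tying together the generators: a random DAG of
#' restrictions with birth rates for `"representable"`, the same with fitness
#' graph pruning for `"local_maxima"`, and `rmf_landscape` for `"rmf"`.
#'
#' @param kind one of `"representable"`, `"local_maxima"`, `"rmf"`.
#' @param n_genes number of genes.
#' @param density edge density of the random DAG (DAG-derived kinds).
#' @param removal_fraction,n_tries pruning parameters (`"local_maxima"`).
#' @param slope_c,hoc_sd RMF parameters.
#' @return a `fitness_landscape`.
#' @export
generate_landscape <- function(kind = c("representable", "local_maxima", "rmf"),
                               n_genes = 7L, density = 0.3,
                               removal_fraction = 0.5, n_tries = 50L,
                               slope_c = 0.05, hoc_sd = 0.03) {
  kind <- match.arg(kind)
  if (kind == "rmf") return(rmf_landscape(n_genes, slope_c, hoc_sd))
  fg <- fitness_graph_from_dag(generate_random_dag(n_genes, density))
  if (kind == "local_maxima")
    fg <- prune_to_local_maxima(fg, removal_fraction, n_tries)
  assign_birth_rates(fg)
}

#' @export
print.fitness_landscape <- function(x, ...) {
  st <- landscape_stats(x)
  cat("Fitness landscape (", x$kind, "), K = ", x$n_genes, "\n",
      "  accessible genotypes: ", st$n_accessible,
      "; local maxima: ", st$n_local_maxima, "\n", sep = "")
  invisible(x)
}

#' @export
print.cpm_poset <- function(x, ...) {
  cat("DAG of restrictions over", x$n_genes, "genes;",
      nrow(x$edges), "gene-to-gene edges\n")
  if (nrow(x$edges))
    cat(paste0("  ", x$labels[x$edges[, 1]], " -> ", x$labels[x$edges[, 2]],
               collapse = "\n"), "\n")
  invisible(x)
}
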