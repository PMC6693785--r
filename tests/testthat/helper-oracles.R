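# Independent straight-line oracles used to check the optimized
# implementations.

# brute-force accessible genotypes of a DAG of restrictions: test every
# genotype against the AND rule, gene by gene
oracle_accessible <- function(dag) {
  K <- dag$n_genes
  ok <- integer(0)
  for (g in 0:(2^K - 1)) {
    bits <- as.integer(intToBits(g))[1:K]
    good <- TRUE
    for (j in which(bits == 1L)) {
      parents <- dag$edges[dag$edges[, 2] == j, 1]
      if (any(bits[parents] == 0L)) good <- FALSE
    }
    if (good) ok <- c(ok, g)
  }
  ok
}

# exhaustive source-to-sink path enumeration on a fitness graph by
# depth-first search over the explicit edge list
oracle_graph_paths <- function(fgraph) {
  sinks <- fgraph$nodes[!(fgraph$nodes %in% fgraph$edges[, 1])]
  paths <- list()
  walk <- function(node, acc) {
    nxt <- fgraph$edges[fgraph$edges[, 1] == node, 2]
    if (!length(nxt)) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    for (h in nxt) walk(h, c(acc, h))
  }
  walk(0L, 0L)
  paths
}

# plain Jensen-Shannon divergence, base 2, from the definition
oracle_js <- function(P, Q) {
  keys <- union(names(P), names(Q))
  tot <- 0
  for (k in keys) {
    p <- if (k %in% names(P)) unname(P[k]) else 0
    q <- if (k %in% names(Q)) unname(Q[k]) else 0
    m <- (p + q) / 2
    if (p > 0) tot <- tot + 0.5 * p * log2(p / m)
    if (q > 0) tot <- tot + 0.5 * q * log2(q / m)
  }
  tot
}

# literal transcription of the unequal-length comparison procedure:
# per terminal length k of the LOD paths, do explicit pairwise prefix
# matching with fractional accounting, then weight the per-group statistics
# by w_k. Written with plain loops, independently of the package internals.
oracle_compare <- function(lod, cpm, renormalize = TRUE) {
  first_k <- function(path, k) paste(strsplit(path, ">")[[1]][seq_len(k)],
                                     collapse = ">")
  len <- function(path) if (nchar(path) == 0) 0L else
    length(strsplit(path, ">")[[1]])
  Kc <- len(names(cpm)[1])
  ks <- vapply(names(lod), len, integer(1))
  js <- rec <- prec <- 0
  for (k in sort(unique(ks))) {
    sel <- ks == k
    pk <- lod[sel]
    wk <- sum(pk)
    if (renormalize) pk <- pk / wk
    P <- numeric(0); Q <- numeric(0)
    p_un <- 0; q_un <- 0
    if (k <= Kc) {
      used <- rep(FALSE, length(cpm))
      for (i in seq_along(pk)) {
        hit <- which(vapply(names(cpm), function(cp) {
          first_k(cp, k) == names(pk)[i]
        }, logical(1)))
        if (length(hit)) {
          P <- c(P, unname(pk[i]))
          Q <- c(Q, sum(cpm[hit]) * k / Kc)
          q_un <- q_un + sum(cpm[hit]) * (Kc - k) / Kc
          used[hit] <- TRUE
          if (k < Kc) rec <- rec # matched shorter LOD fully accounted
        } else {
          p_un <- p_un + unname(pk[i])
        }
      }
      q_un <- q_un + sum(cpm[!used])
    } else {
      prefs <- vapply(names(pk), function(x) first_k(x, Kc), character(1))
      usedq <- rep(FALSE, length(cpm))
      for (pref in unique(prefs)) {
        mass <- sum(pk[prefs == pref])
        hit <- which(names(cpm) == pref)
        if (length(hit)) {
          P <- c(P, mass * Kc / k)
          Q <- c(Q, unname(cpm[hit]))
          p_un <- p_un + mass * (k - Kc) / k
          usedq[hit] <- TRUE
        } else {
          p_un <- p_un + mass
        }
      }
      q_un <- q_un + sum(cpm[!usedq])
    }
    P <- c(P, p_un, 0); Q <- c(Q, 0, q_un)
    names(P) <- names(Q) <- paste0("e", seq_along(P))
    gw <- if (renormalize) wk else 1
    js <- js + gw * oracle_js(P[P > 0], Q[Q > 0])
    rec <- rec + (if (renormalize) wk else 1) * p_un
    prec <- prec + wk * q_un
  }
  list(js = js, one_minus_recall = rec, one_minus_precision = prec)
}

# random mixed-length comparison instance over at most `maxK` features:
# a single-length CPM distribution plus a LOD distribution whose paths are
# truncations/extensions of CPM paths (shared prefixes) mixed with
# unrelated paths
rand_instance <- function(maxK = 6) {
  labels <- paste0("F", seq_len(maxK))
  Kc <- sample(2:maxK, 1)
  cpm <- rand_dist(rand_paths(sample(2:8, 1), Kc, labels))
  lod_paths <- character(0)
  for (i in seq_len(sample(2:10, 1))) {
    k <- sample(seq_len(maxK), 1)
    base <- sample(names(cpm), 1)
    feats <- strsplit(base, ">")[[1]]
    p <- if (k <= Kc) paste(feats[seq_len(k)], collapse = ">")
         else paste(c(feats, sample(setdiff(labels, feats),
                                    min(k - Kc, maxK - Kc))), collapse = ">")
    lod_paths <- c(lod_paths, p)
    if (stats::runif(1) < 0.4)
      lod_paths <- c(lod_paths,
                     paste(sample(labels, sample(seq_len(maxK), 1)),
                           collapse = ">"))
  }
  list(lod = rand_dist(unique(lod_paths)), cpm = cpm)
}
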