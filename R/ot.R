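## Oncogenetic trees: maximum-weight branching over pairwise weights that
## combine joint and marginal frequencies, with edge weights interpreted as
## conditional transition probabilities by observation time.

#' Fit an oncogenetic tree
#'
#' Pairwise weights `w_ij = 2 log p_ij - log(p_i + p_j) - log p_i - log p_j`
#' are computed from the marginal and joint feature frequencies (Root has
#' frequency 1). The weight is symmetric, so the maximum-weight branching
#' rooted at Root is the maximum spanning tree over Root plus the features,
#' oriented away from Root. Edge weights for path extraction are the
#' estimated conditional probabilities `P(child | parent)`.
#'
#' Degenerate columns (frequency 0 or 1) have their frequencies clamped to
#' `1/(2n)` away from the boundary, with a warning.
#'
#' @param dataset a `cpm_dataset` (n >= 2 subjects).
#' @return object of class `ot_model`: `parent` (0 = Root), `weight`
#'   (per-feature conditional probability of occurring given its parent has),
#'   `labels`, `n_genes`. Deterministic given the data.
#' @export
fit_ot <- function(dataset) {
  stopifnot(inherits(dataset, "cpm_dataset"))
  x <- dataset$x
  n <- nrow(x); K <- ncol(x)
  stopifnot(n >= 2, K >= 1)
  eps <- 1 / (2 * n)
  pi <- colMeans(x)
  if (any(pi <= 0 | pi >= 1))
    warning("degenerate feature frequencies clamped: ",
            paste(dataset$labels[pi <= 0 | pi >= 1], collapse = ", "))
  pi <- pmin(pmax(pi, eps), 1 - eps)
  pij <- crossprod(x) / n
  pij <- pmin(pmax(pij, eps^2), 1 - eps)
  ## symmetric weight matrix over Root (index 1) + features (2..K+1)
  W <- matrix(-Inf, K + 1, K + 1)
  for (i in seq_len(K))
    for (j in seq_len(K))
      if (i != j)
        W[i + 1, j + 1] <- 2 * log(pij[i, j]) - log(pi[i] + pi[j]) -
          log(pi[i]) - log(pi[j])
  W[1, 2:(K + 1)] <- W[2:(K + 1), 1] <- log(pi) - log(1 + pi)
  ## Prim's maximum spanning tree from Root; deterministic tie-break by index
  in_tree <- c(TRUE, rep(FALSE, K))
  parent <- integer(K)
  best_w <- W[1, ]
  best_from <- rep(1L, K + 1)
  for (step in seq_len(K)) {
    cand <- which(!in_tree)
    v <- cand[which.max(best_w[cand])]
    in_tree[v] <- TRUE
    parent[v - 1L] <- best_from[v] - 1L
    upd <- !in_tree & W[v, ] > best_w
    best_w[upd] <- W[v, upd]
    best_from[upd] <- v
  }
  weight <- vapply(seq_len(K), function(j) {
    if (parent[j] == 0L) pi[j] else pij[parent[j], j] / pi[parent[j]]
  }, numeric(1))
  weight <- pmin(pmax(weight, eps), 1)
  structure(list(n_genes = K, labels = dataset$labels,
                 parent = parent, weight = unname(weight)),
            class = "ot_model")
}

#' @export
print.ot_model <- function(x, ...) {
  cat("Oncogenetic tree over", x$n_genes, "features\n")
  par <- ifelse(x$parent == 0L, "Root", x$labels[pmax(x$parent, 1L)])
  cat(paste0("  ", par, " -> ", x$labels,
             sprintf("  (w = %.3f)", x$weight), collapse = "\n"), "\n")
  invisible(x)
}
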