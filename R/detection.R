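## Detection regimes: convert trajectory collections into cross-sectional
## binary data sets, and split them into non-overlapping CPM input samples.

#' Detection regime on log tumor size
#'
#' Sampling times are chosen by drawing a Beta deviate and rescaling it to
#' the range of observed log tumor sizes: `B(1,1)` (uniform), `B(5,3)`
#' (large: samples enriched in large tumors, late detection) or `B(3,5)`
#' (small: early detection).
#'
#' @param name `"uniform"`, `"large"` or `"small"`.
#' @return object of class `detection_regime` with `alpha`, `beta`.
#' @export
detection_regime <- function(name = c("uniform", "large", "small")) {
  name <- match.arg(name)
  par <- switch(name, uniform = c(1, 1), large = c(5, 3), small = c(3, 5))
  structure(list(name = name, alpha = par[1], beta = par[2]),
            class = "detection_regime")
}

#' Sample one observed genotype per trajectory under a detection regime
#'
#' For each trajectory a fresh Beta deviate is rescaled to the range of log
#' population sizes (pooled across all trajectories by default), the
#' snapshot with closest log size is selected (ties toward the earlier
#' snapshot), and the genotype of its most abundant clone is returned.
#'
#' @param trajectories list of snapshot data frames (or of `cpm_trajectory`).
#' @param regime a `detection_regime`.
#' @param pool `"pooled"` rescales to the min/max of log sizes pooled over
#'   all trajectories; `"per_trajectory"` uses each trajectory's own range.
#' @return integer vector of genotype bitmasks, one per trajectory.
#' @export
sample_detection <- function(trajectories, regime = detection_regime(),
                             pool = c("pooled", "per_trajectory")) {
  pool <- match.arg(pool)
  stopifnot(inherits(regime, "detection_regime"))
  if (!length(trajectories)) stop("empty trajectory list")
  snaps <- lapply(trajectories, function(tr) {
    if (inherits(tr, "cpm_trajectory")) tr$snapshots else tr
  })
  if (any(!vapply(snaps, nrow, integer(1))))
    stop("every trajectory needs at least one snapshot")
  logs <- lapply(snaps, function(s) log(s$size))
  if (pool == "pooled") {
    rng <- range(unlist(logs))
    lo <- rep(rng[1], length(snaps)); hi <- rep(rng[2], length(snaps))
  } else {
    lo <- vapply(logs, min, numeric(1)); hi <- vapply(logs, max, numeric(1))
  }
  dev <- stats::rbeta(length(snaps), regime$alpha, regime$beta)
  target <- lo + dev * (hi - lo)
  vapply(seq_along(snaps), function(i) {
    snaps[[i]]$top_geno[which.min(abs(logs[[i]] - target[i]))]
  }, integer(1))
}

#' Build a cross-sectional binary data set from sampled genotypes
#'
#' @param genotypes integer vector of genotype bitmasks.
#' @param n_genes number of features K.
#' @param labels feature names (unique).
#' @param provenance optional free-form provenance list.
#' @return object of class `cpm_dataset`: binary matrix `x` of subjects by
#'   features, plus `labels` and `provenance`. All-zero columns are kept.
#' @export
build_dataset <- function(genotypes, n_genes,
                          labels = default_labels(n_genes),
                          provenance = list()) {
  n_genes <- check_n_genes(n_genes)
  stopifnot(length(labels) == n_genes, !anyDuplicated(labels),
            length(genotypes) >= 1)
  if (any(genotypes < 0L | genotypes >= 2L^n_genes))
    stop("genotype bitmask out of range for n_genes = ", n_genes)
  x <- vapply(seq_len(n_genes), function(j) {
    as.integer(bitwAnd(genotypes, bitwShiftL(1L, j - 1L)) > 0L)
  }, integer(length(genotypes)))
  x <- matrix(x, ncol = n_genes, dimnames = list(NULL, labels))
  structure(list(x = x, labels = labels, provenance = provenance),
            class = "cpm_dataset")
}

#' Split a data set into non-overlapping subsets
#'
#' For each requested size, `n_splits` pairwise-disjoint subsets are drawn
#' without replacement from the rows.
#'
#' @param dataset a `cpm_dataset`.
#' @param sizes vector of subset sizes.
#' @param n_splits number of disjoint subsets per size.
#' @return list (one element per size, named by size) of lists of
#'   `cpm_dataset` splits.
#' @export
split_nonoverlapping <- function(dataset, sizes, n_splits = 5L) {
  stopifnot(inherits(dataset, "cpm_dataset"))
  n <- nrow(dataset$x)
  bad <- sizes[n_splits * sizes > n]
  if (length(bad))
    stop("insufficient samples: need ", n_splits, " x ", bad[1],
         " = ", n_splits * bad[1], " rows but have ", n)
  out <- lapply(sizes, function(s) {
    rows <- sample.int(n, n_splits * s)
    lapply(seq_len(n_splits), function(k) {
      idx <- rows[((k - 1L) * s + 1L):(k * s)]
      ds <- dataset
      ds$x <- dataset$x[idx, , drop = FALSE]
      ds$provenance <- c(dataset$provenance, list(size = s, split = k))
      ds
    })
  })
  names(out) <- as.character(sizes)
  out
}

#' Keep the most common features of a data set
#'
#' Retains the `threshold` columns with the highest mutation frequency (ties
#' broken by column order). Data sets with at most `threshold` features are
#' returned unchanged.
#'
#' @param dataset a `cpm_dataset`.
#' @param threshold number of features to keep (the study uses 7, 10, 12).
#' @return a `cpm_dataset`.
#' @export
top_features <- function(dataset, threshold) {
  stopifnot(inherits(dataset, "cpm_dataset"), threshold >= 1)
  if (ncol(dataset$x) <= threshold) return(dataset)
  keep <- sort(order(colMeans(dataset$x), decreasing = TRUE)[seq_len(threshold)])
  dataset$x <- dataset$x[, keep, drop = FALSE]
  dataset$labels <- dataset$labels[keep]
  dataset
}

#' @export
print.cpm_dataset <- function(x, ...) {
  cat("Cross-sectional data set:", nrow(x$x), "subjects x",
      ncol(x$x), "features\n")
  invisible(x)
}
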