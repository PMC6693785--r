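## Mutational paths to the maximum and probability distributions over them.
## A path is written as feature labels joined by ">" in order of
## acquisition ("" is the empty path of the wild type). A path distribution
## is a named numeric vector of probabilities of class `path_distribution`.

new_path_distribution <- function(p, tol = 1e-9) {
  if (!length(p)) stop("empty path distribution")
  if (any(p < 0)) stop("negative path probability")
  if (abs(sum(p) - 1) > tol)
    stop("path probabilities must sum to 1 (got ", sum(p), ")")
  if (anyDuplicated(names(p))) stop("duplicated paths")
  structure(p / sum(p), class = "path_distribution")
}

#' Lengths (number of mutations) of paths in a distribution or path set
#' @param paths character vector of `>`-joined paths.
#' @return integer vector.
#' @export
path_lengths <- function(paths) {
  keys <- if (is.null(names(paths))) paths else names(paths)
  ifelse(nchar(keys) == 0L, 0L,
         lengths(strsplit(keys, ">", fixed = TRUE)))
}

## shared depth-first enumeration of the linear extensions of a poset given
## by direct-parent bitmasks; weight_fun(avail_genes) returns transition
## probabilities (NULL enumerates without weights)
enumerate_extensions <- function(parent_masks, labels, weight_fun = NULL,
                                 cap = 1e6) {
  K <- length(parent_masks)
  acc <- new.env(parent = emptyenv())
  acc$paths <- character(0)
  acc$probs <- numeric(0)
  acc$count <- 0L
  bits <- bitwShiftL(1L, seq_len(K) - 1L)
  recurse <- function(state, prefix, prob) {
    avail <- which(bitwAnd(state, bits) == 0L &
                   bitwAnd(state, parent_masks) == parent_masks)
    if (!length(avail)) {
      acc$count <- acc$count + 1L
      if (acc$count > cap)
        stop("more than ", cap, " paths; raise `cap` or stream over paths")
      acc$paths[acc$count] <- paste(prefix, collapse = ">")
      acc$probs[acc$count] <- prob
      return(invisible())
    }
    w <- if (is.null(weight_fun)) rep(1, length(avail)) else weight_fun(avail)
    w <- w / sum(w)
    for (a in seq_along(avail)) {
      recurse(bitwOr(state, bits[avail[a]]),
              c(prefix, labels[avail[a]]),
              prob * w[a])
    }
  }
  recurse(0L, character(0), 1)
  list(paths = acc$paths, probs = acc$probs)
}

model_parent_masks <- function(model) {
  if (inherits(model, "cpm_poset")) poset_parent_masks(model)
  else if (inherits(model, "cbn_model")) poset_parent_masks(model$poset)
  else if (inherits(model, "ot_model")) {
    vapply(model$parent, function(p) {
      if (p == 0L) 0L else bitwShiftL(1L, p - 1L)
    }, integer(1))
  } else stop("unsupported model type")
}

model_labels <- function(model) {
  if (inherits(model, "cpm_poset")) model$labels else model$labels
}

#' Set of mutational paths to the maximum encoded by a model
#'
#' The paths are the linear extensions of the poset (or tree), i.e. the
#' source-to-sink paths of the model's fitness graph; all end at the fully
#' mutated genotype.
#'
#' @param model a `cpm_poset`, `cbn_model` or `ot_model`.
#' @param cap maximum number of paths to materialize (default 1e6).
#' @return character vector of paths.
#' @export
paths_from_model <- function(model, cap = 1e6) {
  enumerate_extensions(model_parent_masks(model), model_labels(model),
                       NULL, cap)$paths
}

#' Probability-weighted paths of a CBN model
#'
#' The probability of a path is the product over its steps of
#' `lambda_next / sum(lambda_available)`, with a feature available once its
#' poset parents are mutated (competing exponential waiting times).
#'
#' @param model a `cbn_model`.
#' @param cap path cap.
#' @return a `path_distribution`.
#' @export
weight_paths_cbn <- function(model, cap = 1e6) {
  stopifnot(inherits(model, "cbn_model"))
  lam <- model$lambda
  res <- enumerate_extensions(poset_parent_masks(model$poset), model$labels,
                              function(avail) lam[avail], cap)
  new_path_distribution(stats::setNames(res$probs, res$paths))
}

#' Probability-weighted paths of an oncogenetic tree
#'
#' At each genotype the transition probability to each available next
#' feature is proportional to its OT edge weight (`mode = "proportional"`,
#' the default) or follows independent Bernoulli occurrence of the remaining
#' events (`mode = "bernoulli"`, normalized over full paths).
#'
#' @param model an `ot_model`.
#' @param mode `"proportional"` or `"bernoulli"`.
#' @param cap path cap.
#' @return a `path_distribution`.
#' @export
weight_paths_ot <- function(model, mode = c("proportional", "bernoulli"),
                            cap = 1e6) {
  stopifnot(inherits(model, "ot_model"))
  mode <- match.arg(mode)
  pm <- model_parent_masks(model)
  w <- model$weight
  res <- enumerate_extensions(pm, model$labels,
                              function(avail) w[avail], cap)
  p <- res$probs
  if (mode == "bernoulli") {
    ## product of edge weights along the path, renormalized over paths
    p <- vapply(strsplit(res$paths, ">", fixed = TRUE), function(feats) {
      prod(w[match(feats, model$labels)])
    }, numeric(1))
    p <- p / sum(p)
  }
  new_path_distribution(stats::setNames(p, res$paths))
}

#' Uniform distribution over a set of paths
#'
#' @param paths non-empty character vector of distinct paths.
#' @return a `path_distribution` giving each path probability `1/n`.
#' @export
uniform_path_distribution <- function(paths) {
  if (!length(paths)) stop("empty path set")
  paths <- unique(paths)
  new_path_distribution(stats::setNames(rep(1 / length(paths),
                                            length(paths)), paths))
}

#' Empirical path distribution of a collection of LODs
#'
#' @param lods list of `cpm_lod` objects, or a character vector of
#'   `>`-joined paths (one entry per simulated run).
#' @return a `path_distribution` of relative path frequencies; path lengths
#'   may differ.
#' @export
lod_path_distribution <- function(lods) {
  if (!length(lods)) stop("empty LOD collection")
  keys <- if (is.character(lods)) lods
          else vapply(lods, function(l) path_key(l$path), character(1))
  tab <- table(keys)
  new_path_distribution(stats::setNames(as.numeric(tab) / length(keys),
                                        names(tab)))
}

#' @export
print.path_distribution <- function(x, n = 6L, ...) {
  cat("Path distribution over", length(x), "paths\n")
  top <- sort(unclass(x), decreasing = TRUE)
  show <- utils::head(top, n)
  for (i in seq_along(show))
    cat(sprintf("  %-40s %.4f\n", names(show)[i], show[i]))
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}
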