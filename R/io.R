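## Plain-text serialization: landscapes and models as JSON, data sets as
## CSV, path distributions as TSV, DAGs as DOT / edge-list TSV.

#' Write / read a fitness landscape as JSON
#'
#' Genotypes are stored as bitstrings with their birth rates; provenance
#' (DAG edges, pruned fitness-graph edges, or RMF parameters) is embedded.
#'
#' @param landscape a `fitness_landscape`.
#' @param path file path.
#' @export
write_landscape <- function(landscape, path) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  K <- landscape$n_genes
  obj <- list(n_genes = K, kind = landscape$kind, labels = landscape$labels,
              genotypes = geno_string(0:(2L^K - 1L), K),
              birth_rate = landscape$birth_rate)
  if (landscape$kind == "rmf") {
    obj$provenance <- list(reference = geno_string(landscape$provenance$reference, K),
                           slope_c = landscape$provenance$slope_c,
                           hoc_sd = landscape$provenance$hoc_sd)
  } else {
    obj$provenance <- list(
      dag_edges = landscape$graph$dag$edges,
      graph_edges = cbind(geno_string(landscape$graph$edges[, 1], K),
                          geno_string(landscape$graph$edges[, 2], K)),
      pruned = landscape$graph$pruned)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- as.integer(obj$n_genes)
  rate <- as.numeric(obj$birth_rate)
  if (obj$kind == "rmf") {
    return(structure(list(n_genes = K, labels = obj$labels,
                          birth_rate = rate, kind = "rmf",
                          provenance = list(
                            reference = geno_mask(obj$provenance$reference),
                            slope_c = obj$provenance$slope_c,
                            hoc_sd = obj$provenance$hoc_sd)),
                     class = "fitness_landscape"))
  }
  dag <- new_poset(K, matrix(as.integer(obj$provenance$dag_edges), ncol = 2),
                   obj$labels)
  ge <- matrix(obj$provenance$graph_edges, ncol = 2)
  edges <- cbind(from = geno_mask(ge[, 1]), to = geno_mask(ge[, 2]))
  nodes <- sort(unique(c(0L, edges)))
  graph <- structure(list(n_genes = K, labels = obj$labels, nodes = nodes,
                          edges = edges, pruned = isTRUE(obj$provenance$pruned),
                          dag = dag),
                     class = "fitness_graph")
  structure(list(n_genes = K, labels = obj$labels, birth_rate = rate,
                 kind = obj$kind, graph = graph),
            class = "fitness_landscape")
}

#' Write / read a cross-sectional data set as CSV
#'
#' Comma-separated, header row of feature names, one subject per row,
#' values 0/1, no row names. Round-trips bit-exactly.
#'
#' @param dataset a `cpm_dataset`.
#' @param path file path.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "cpm_dataset"))
  utils::write.csv(as.data.frame(dataset$x), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df)
  storage.mode(x) <- "integer"
  if (any(!(x %in% c(0L, 1L)))) stop("dataset entries must be 0/1")
  structure(list(x = x, labels = colnames(x),
                 provenance = list(source = path)),
            class = "cpm_dataset")
}

#' Write / read a path distribution as TSV
#'
#' Two columns: `path` (features joined by `>`) and `prob`. The reader
#' validates that probabilities sum to 1.
#'
#' @param dist a `path_distribution`.
#' @param path file path.
#' @export
write_path_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "path_distribution"))
  utils::write.table(data.frame(path = names(dist),
                                prob = as.numeric(dist)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_path_distribution
#' @export
read_path_distribution <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "numeric"))
  new_path_distribution(stats::setNames(df$prob, df$path), tol = 1e-6)
}

#' Export a DAG of restrictions as DOT or edge-list TSV
#'
#' @param poset a `cpm_poset`.
#' @param path file path.
#' @export
poset_to_dot <- function(poset, path) {
  stopifnot(inherits(poset, "cpm_poset"))
  rooted <- setdiff(seq_len(poset$n_genes), poset$edges[, 2])
  lines <- c("digraph poset {",
             paste0("  Root -> ", poset$labels[rooted], ";"),
             if (nrow(poset$edges))
               paste0("  ", poset$labels[poset$edges[, 1]], " -> ",
                      poset$labels[poset$edges[, 2]], ";"),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname poset_to_dot
#' @export
poset_to_tsv <- function(poset, path) {
  stopifnot(inherits(poset, "cpm_poset"))
  utils::write.table(data.frame(parent = poset$labels[poset$edges[, 1]],
                                child = poset$labels[poset$edges[, 2]]),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a fitted CPM model as JSON
#'
#' @param model an `ot_model` or `cbn_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "cbn_model")) {
    obj <- list(type = "cbn", n_genes = model$n_genes, labels = model$labels,
                poset_edges = model$poset$edges, lambda = model$lambda,
                eps = model$eps)
  } else if (inherits(model, "ot_model")) {
    obj <- list(type = "ot", n_genes = model$n_genes, labels = model$labels,
                parent = model$parent, weight = model$weight)
  } else stop("unsupported model")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "cbn") {
    poset <- new_poset(as.integer(obj$n_genes),
                       matrix(as.integer(obj$poset_edges), ncol = 2),
                       obj$labels)
    cbn_model(poset, as.numeric(obj$lambda), obj$eps)
  } else {
    structure(list(n_genes = as.integer(obj$n_genes), labels = obj$labels,
                   parent = as.integer(obj$parent),
                   weight = as.numeric(obj$weight)),
              class = "ot_model")
  }
}
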