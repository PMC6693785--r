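## Factorial benchmark orchestration: design enumeration, scaled-down
## execution, and result summaries.

#' Enumerate the factorial simulation design
#'
#' The full design crosses 2 gene counts (7, 10) x 3 landscape kinds x 3
#' initial population sizes (2000, 50000, 1e6) x 2 mutation regimes x 35
#' landscape replicates = 1260 landscape configurations; each is sampled
#' under 3 detection regimes and split into 5 non-overlapping data sets for
#' each of 3 sample sizes (50, 200, 4000), giving 56700 data sets, with
#' 20000 evolutionary runs per landscape. The desk scale shrinks only
#' replicate counts and run numbers (7 genes, N0 = 2000, constant mutation
#' regime, 5 replicates, 1000 runs, sample sizes 50/200/1000), never the
#' factor structure; split counts are truncated at run time when
#' `n_splits * size` exceeds the number of runs.
#'
#' @param scale `"full"` or `"desk"`.
#' @param replicates override the number of landscape replicates.
#' @param n_runs override the evolutionary runs per landscape.
#' @return object of class `experiment_design` with data frames
#'   `landscapes` and `datasets`.
#' @export
enumerate_design <- function(scale = c("full", "desk"), replicates = NULL,
                             n_runs = NULL) {
  scale <- match.arg(scale)
  if (scale == "full") {
    genes <- c(7L, 10L); inits <- c(2000, 50000, 1e6)
    regimes <- c("constant", "variable")
    reps <- if (is.null(replicates)) 35L else replicates
    sizes <- c(50L, 200L, 4000L)
    runs <- if (is.null(n_runs)) 20000L else n_runs
  } else {
    genes <- 7L; inits <- 2000
    regimes <- "constant"
    reps <- if (is.null(replicates)) 5L else replicates
    sizes <- c(50L, 200L, 1000L)
    runs <- if (is.null(n_runs)) 1000L else n_runs
  }
  kinds <- c("representable", "local_maxima", "rmf")
  landscapes <- expand.grid(n_genes = genes, kind = kinds,
                            init_size = inits, regime = regimes,
                            replicate = seq_len(reps),
                            stringsAsFactors = FALSE)
  landscapes$landscape_id <- seq_len(nrow(landscapes))
  datasets <- merge(landscapes,
                    expand.grid(detection = c("uniform", "large", "small"),
                                size = sizes, split = 1:5,
                                stringsAsFactors = FALSE))
  structure(list(landscapes = landscapes, datasets = datasets,
                 scale = scale, n_runs = runs, sizes = sizes,
                 n_splits = 5L),
            class = "experiment_design")
}

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 104729) %% 2147483587)
}

## run one landscape configuration end to end; returns result rows
run_landscape_cell <- function(row, n_runs, sizes, n_splits, cpms,
                               control, detections = c("uniform", "large",
                                                       "small"),
                               max_regen = 20L) {
  K <- row$n_genes
  for (regen in seq_len(max_regen)) {
    landscape <- generate_landscape(row$kind, n_genes = K)
    regime <- mutation_regime(row$regime, K)
    sim <- batch_simulate(landscape, sim_config(init_size = row$init_size),
                          regime, n_runs = n_runs)
    if (sim$all_genes_covered) break
  }
  if (!sim$all_genes_covered)
    stop("gene coverage not achieved after ", max_regen, " landscapes")
  lod_dist <- lod_path_distribution(sim$paths)
  s_p <- path_entropy(lod_dist)
  out <- list()
  for (det in detections) {
    genotypes <- sample_detection(sim$trajectories, detection_regime(det))
    full_ds <- build_dataset(genotypes, K, landscape$labels)
    for (s in sizes) {
      k_splits <- min(n_splits, floor(n_runs / s))
      if (k_splits < 1L) next
      splits <- split_nonoverlapping(full_ds, s, k_splits)[[1]]
      for (sp in seq_len(k_splits)) {
        for (cpm in cpms) {
          res <- tryCatch({
            if (cpm == "cbn") {
              fit <- fit_cbn(splits[[sp]], control)
              wdist <- weight_paths_cbn(fit)
            } else {
              fit <- fit_ot(splits[[sp]])
              wdist <- weight_paths_ot(fit)
            }
            udist <- uniform_path_distribution(names(wdist))
            cw <- compare_path_distributions(lod_dist, wdist)
            cu <- compare_path_distributions(lod_dist, udist)
            mcl <- most_common_lod_recovered(lod_dist, names(wdist))
            rbind(
              data.frame(weighting = "probability", js = cw$js,
                         one_minus_recall = cw$one_minus_recall,
                         one_minus_precision = cw$one_minus_precision,
                         s_c = path_entropy(wdist), mcl = mcl,
                         n_paths_cpm = length(wdist)),
              data.frame(weighting = "uniform", js = cu$js,
                         one_minus_recall = cu$one_minus_recall,
                         one_minus_precision = cu$one_minus_precision,
                         s_c = path_entropy(udist), mcl = mcl,
                         n_paths_cpm = length(udist)))
          }, error = function(e) {
            data.frame(weighting = c("probability", "uniform"),
                       js = NA_real_, one_minus_recall = NA_real_,
                       one_minus_precision = NA_real_, s_c = NA_real_,
                       mcl = NA_integer_, n_paths_cpm = NA_integer_)
          })
          res$cpm <- cpm
          res$detection <- det
          res$size <- s
          res$split <- sp
          out[[length(out) + 1L]] <- res
        }
      }
    }
  }
  rows <- do.call(rbind, out)
  rows$landscape_id <- row$landscape_id
  rows$kind <- row$kind
  rows$n_genes <- K
  rows$init_size <- row$init_size
  rows$regime <- row$regime
  rows$replicate <- row$replicate
  rows$s_p <- s_p
  rows$n_lods <- length(lod_dist)
  rows
}

#' Run the benchmark pipeline over a design
#'
#' For every landscape configuration: generate the landscape (regenerating
#' until every gene is covered by the simulations), run the evolutionary
#' batch, sample each detection regime, split, fit each CPM, weight paths
#' (probability-weighted and uniform) and score against the LOD
#' distribution. Fully reproducible from `master_seed`: each landscape row
#' uses its own derived seed, so any execution order gives identical
#' results. Individual fit failures flag the row's metrics as NA and the run
#' continues.
#'
#' @param design an `experiment_design`.
#' @param master_seed integer master seed.
#' @param cpms CPMs to fit (`"cbn"`, `"ot"`).
#' @param control `cbn_control` for the CBN fits.
#' @param landscape_rows optional subset of `design$landscapes` row indices.
#' @param detections detection regimes to sample (default all three).
#' @return data frame of result rows (one per dataset x CPM x weighting).
#' @export
run_benchmark <- function(design, master_seed = 1L,
                          cpms = c("cbn", "ot"),
                          control = cbn_control(),
                          landscape_rows = NULL,
                          detections = c("uniform", "large", "small")) {
  stopifnot(inherits(design, "experiment_design"))
  idx <- if (is.null(landscape_rows)) seq_len(nrow(design$landscapes))
         else landscape_rows
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    row <- design$landscapes[idx[i], ]
    set.seed(derive_seed(master_seed, row$landscape_id))
    out[[i]] <- run_landscape_cell(row, design$n_runs, design$sizes,
                                   design$n_splits, cpms, control,
                                   detections = detections)
  }
  do.call(rbind, out)
}

#' Summarize benchmark result rows
#'
#' Averages the five split replicates within each landscape x detection x
#' sample-size x CPM x weighting cell (the response convention of the
#' study), then reports group means and SDs per landscape kind x detection
#' x sample size x CPM x weighting, including the mean S_c/S_p ratio.
#'
#' @param rows result rows from [run_benchmark()].
#' @return list with `responses` (split-averaged rows) and `summary`.
#' @export
summarize_results <- function(rows) {
  stopifnot(nrow(rows) >= 1)
  resp_keys <- c("landscape_id", "kind", "n_genes", "init_size", "regime",
                 "detection", "size", "cpm", "weighting")
  metrics <- c("js", "one_minus_recall", "one_minus_precision",
               "s_c", "s_p", "mcl")
  responses <- stats::aggregate(rows[metrics], rows[resp_keys], mean,
                                na.rm = TRUE)
  responses$sc_sp_ratio <- responses$s_c / responses$s_p
  sum_keys <- c("kind", "detection", "size", "cpm", "weighting")
  means <- stats::aggregate(responses[c(metrics, "sc_sp_ratio")],
                            responses[sum_keys], mean, na.rm = TRUE)
  sds <- stats::aggregate(responses[c("js")], responses[sum_keys],
                          stats::sd, na.rm = TRUE)
  names(sds)[names(sds) == "js"] <- "js_sd"
  list(responses = responses, summary = merge(means, sds))
}
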