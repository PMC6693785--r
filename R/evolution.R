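## Clonal evolution to fixation and Lines of Descent (LODs).
## The integrators live in src/sim.cpp; this file is the user-facing surface.

#' Per-gene mutation rates under the two mutation regimes
#'
#' `"constant"`: every gene mutates at `rate` (default 1e-5).
#' `"variable"`: iid rates, uniform on the log scale between `rate/5` and
#' `5 * rate`, so the largest max/min ratio is 25, the arithmetic mean of the
#' rates is about 1.5e-5 and the geometric mean 1e-5 at the default `rate`.
#'
#' @param kind `"constant"` or `"variable"`.
#' @param n_genes number of genes.
#' @param rate base mutation rate per gene per division.
#' @return object of class `mutation_regime` with a `rates` vector.
#' @export
mutation_regime <- function(kind = c("constant", "variable"), n_genes,
                            rate = 1e-5) {
  kind <- match.arg(kind)
  n_genes <- check_n_genes(n_genes)
  stopifnot(rate > 0)
  rates <- if (kind == "constant") rep(rate, n_genes)
           else exp(stats::runif(n_genes, log(rate / 5), log(rate * 5)))
  structure(list(kind = kind, rates = rates), class = "mutation_regime")
}

#' Simulation configuration
#'
#' @param init_size initial population size N0 (the study uses 2000, 50000
#'   and 1e6; default 2000).
#' @param fixation_threshold frequency a local-maximum genotype must reach
#'   for the run to stop (theta, default 0.99).
#' @param max_time simulated-time guard; exceeding it triggers a restart.
#' @param method `"tauleap"` (default), `"gillespie"` (exact), or `"auto"`
#'   (exact for small populations, tau-leap above 3000 cells).
#' @param leap_frac tau-leap step control: per-capita event probability per
#'   step (default 0.1).
#' @param snap_dt snapshots are recorded whenever the population size changes
#'   by >= 1% or `snap_dt` time units have elapsed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(init_size = 2000, fixation_threshold = 0.99,
                       max_time = 1e6,
                       method = c("tauleap", "gillespie", "auto"),
                       leap_frac = 0.1, snap_dt = 25) {
  method <- match.arg(method)
  stopifnot(init_size >= 1, fixation_threshold > 0.5,
            fixation_threshold <= 1, max_time > 0)
  if (method == "auto")
    method <- if (init_size <= 3000) "gillespie" else "tauleap"
  structure(list(init_size = init_size,
                 fixation_threshold = fixation_threshold,
                 max_time = max_time, method = method,
                 leap_frac = leap_frac, snap_dt = snap_dt),
            class = "sim_config")
}

#' Simulate tumor evolution until fixation at a fitness maximum
#'
#' Runs the density-dependent birth-death process on a fitness landscape
#' until one of the local fitness maxima holds at least
#' `config$fixation_threshold` of the population. Runs that exceed
#' `config$max_time` (or go extinct) are restarted with a fresh random
#' stream, up to `max_restarts` times.
#'
#' @param landscape a `fitness_landscape`.
#' @param config a `sim_config`.
#' @param regime a `mutation_regime` with matching number of genes.
#' @param max_restarts restarts allowed on timeout/extinction.
#' @return object of class `cpm_trajectory`: `snapshots` data frame
#'   (`time`, `size`, `top_geno`, `top_n`), clone `parent` links (integer
#'   vector over all genotype bitmasks, -1 if never created), `fixated`
#'   genotype bitmask, `status`, `n_genes`, `labels`.
#' @export
simulate_to_fixation <- function(landscape, config = sim_config(),
                                 regime = mutation_regime("constant",
                                                          landscape$n_genes),
                                 max_restarts = 10L) {
  stopifnot(inherits(landscape, "fitness_landscape"),
            inherits(config, "sim_config"),
            inherits(regime, "mutation_regime"),
            length(regime$rates) == landscape$n_genes)
  K <- landscape$n_genes
  is_max <- logical(2L^K)
  is_max[landscape_local_maxima(landscape, "forward") + 1L] <- TRUE
  if (!any(is_max & landscape$birth_rate > 0))
    stop("landscape has no local maximum with positive birth rate")
  for (attempt in seq_len(max_restarts + 1L)) {
    res <- .sim_fixation_cpp(K, landscape$birth_rate, is_max,
                             config$init_size, config$fixation_threshold,
                             config$max_time, regime$rates,
                             if (config$method == "gillespie") 0L else 1L,
                             config$leap_frac, config$snap_dt)
    if (res$status == "fixated") break
  }
  if (res$status != "fixated")
    stop("no fixation after ", max_restarts + 1L, " attempts (last status: ",
         res$status, ")")
  structure(list(snapshots = data.frame(time = res$snap_time,
                                        size = res$snap_size,
                                        top_geno = res$snap_top,
                                        top_n = res$snap_top_n),
                 parent = res$parent, fixated = res$fixated,
                 status = res$status, final_time = res$final_time,
                 n_genes = K, labels = landscape$labels),
            class = "cpm_trajectory")
}

#' Extract the Line of Descent of a trajectory
#'
#' Traces the clone-ancestry links of the fixated genotype back to the wild
#' type. Each step of the LOD adds exactly one mutation (no back mutations).
#'
#' @param trajectory a `cpm_trajectory` that reached fixation.
#' @return object of class `cpm_lod`: `genotypes` (bitmask sequence from 0 to
#'   the fixated genotype) and `path` (gene labels in acquisition order).
#' @export
extract_lod <- function(trajectory) {
  stopifnot(inherits(trajectory, "cpm_trajectory"),
            trajectory$status == "fixated")
  g <- trajectory$fixated
  chain <- g
  while (g != 0L) {
    p <- trajectory$parent[g + 1L]
    if (p < 0L || popcount(bitwXor(g, p)) != 1L)
      stop("broken ancestry chain at genotype ",
           geno_string(g, trajectory$n_genes))
    chain <- c(p, chain)
    g <- p
  }
  added <- vapply(seq_along(chain)[-1], function(i) {
    mask_genes(bitwXor(chain[i], chain[i - 1L]), trajectory$n_genes)
  }, integer(1))
  structure(list(genotypes = chain,
                 path = trajectory$labels[added]),
            class = "cpm_lod")
}

path_key <- function(labels) paste(labels, collapse = ">")

#' Simulate a batch of independent evolutionary processes
#'
#' @param landscape a `fitness_landscape`.
#' @param config a `sim_config`.
#' @param regime a `mutation_regime`.
#' @param n_runs number of independent runs.
#' @param keep_trajectories keep per-run snapshot tables (needed by the
#'   detection module); set `FALSE` to save memory when only LODs are needed.
#' @return list with `lods` (list of `cpm_lod`), `paths` (character vector of
#'   `>`-joined gene paths, one per run), `trajectories` (list or NULL), and
#'   `all_genes_covered`: TRUE iff every gene appeared mutated in at least
#'   one genotype ever created across the runs. When FALSE the caller should
#'   discard the landscape and regenerate.
#' @export
batch_simulate <- function(landscape, config = sim_config(),
                           regime = mutation_regime("constant",
                                                    landscape$n_genes),
                           n_runs = 1000L, keep_trajectories = TRUE) {
  stopifnot(n_runs >= 1)
  lods <- vector("list", n_runs)
  trajs <- if (keep_trajectories) vector("list", n_runs) else NULL
  covered <- 0L
  for (r in seq_len(n_runs)) {
    tr <- simulate_to_fixation(landscape, config, regime)
    lods[[r]] <- extract_lod(tr)
    created <- which(tr$parent >= 0L) - 1L
    covered <- bitwOr(covered, Reduce(bitwOr, created, 0L))
    if (keep_trajectories) trajs[[r]] <- tr$snapshots
  }
  full <- 2L^landscape$n_genes - 1L
  list(lods = lods,
       paths = vapply(lods, function(l) path_key(l$path), character(1)),
       trajectories = trajs,
       all_genes_covered = bitwAnd(covered, full) == full)
}
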