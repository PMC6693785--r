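# Small fixtures built in code.

# The 4-gene DAG of restrictions where a mutation in gene 4 requires
# mutations in both gene 2 AND gene 3; genes 1-3 depend only on Root.
fig_dag <- function() new_poset(4, rbind(c(2L, 4L), c(3L, 4L)))

# a fast configuration for simulation-heavy tests
quick_config <- function(...) sim_config(init_size = 2000, ...)

# deterministic tiny dataset
toy_dataset <- function() {
  x <- rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(0, 0, 0),
             c(1, 1, 0), c(1, 0, 0), c(1, 1, 1), c(0, 0, 0))
  build_dataset(as.integer(x %*% c(1, 2, 4)), 3)
}

# random path distribution over given paths
rand_dist <- function(paths) {
  p <- stats::rgamma(length(paths), 1)
  structure(stats::setNames(p / sum(p), paths), class = "path_distribution")
}

# random permutation paths of length k over labels
rand_paths <- function(n, k, labels) {
  unique(replicate(n, paste(sample(labels, k), collapse = ">")))
}
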