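## Conjunctive Bayesian networks: exact lattice likelihood (src/cbn.cpp),
## a monotone nested parameter fit, simulated annealing over posets, and a
## forward sampler.

#' Construct a CBN model
#'
#' @param poset a `cpm_poset` over the features (conjunctive restrictions).
#' @param lambda positive per-feature waiting-time rates, relative to an
#'   Exp(1) observation time.
#' @param eps symmetric per-bit observation error in \[0, 0.5).
#' @return object of class `cbn_model`.
#' @export
cbn_model <- function(poset, lambda, eps = 0) {
  stopifnot(inherits(poset, "cpm_poset"),
            length(lambda) == poset$n_genes, all(lambda > 0),
            all(is.finite(lambda)), eps >= 0, eps < 0.5)
  structure(list(n_genes = poset$n_genes, labels = poset$labels,
                 poset = poset, lambda = as.numeric(lambda), eps = eps),
            class = "cbn_model")
}

dataset_counts <- function(dataset) {
  K <- ncol(dataset$x)
  masks <- as.integer(dataset$x %*% bitwShiftL(1L, seq_len(K) - 1L))
  tab <- table(masks)
  list(obs = as.integer(names(tab)), counts = as.numeric(tab), K = K,
       n = nrow(dataset$x))
}

#' Exact log-likelihood of a CBN model on a data set
#'
#' Genotype occupancy probabilities of the continuous-time Markov chain on
#' the lattice of poset-compatible genotypes, observed at an Exp(1) sampling
#' time, convolved with the symmetric bit-flip error `eps`. With `eps = 0`
#' an observation incompatible with the poset yields `-Inf`.
#'
#' @param model a `cbn_model`.
#' @param dataset a `cpm_dataset` with matching features.
#' @return log-likelihood value.
#' @export
cbn_loglik <- function(model, dataset) {
  stopifnot(inherits(model, "cbn_model"),
            ncol(dataset$x) == model$n_genes)
  dc <- dataset_counts(dataset)
  .cbn_loglik_cpp(dc$K, poset_parent_masks(model$poset), model$lambda,
                  model$eps, dc$obs, dc$counts)
}

#' Genotype occupancy probabilities of a CBN model
#'
#' @param model a `cbn_model`.
#' @return data frame with `genotype` (bitstring), `mask` and `prob`; the
#'   probability of observing each poset-compatible genotype at an Exp(1)
#'   sampling time (before observation error).
#' @export
cbn_genotype_probs <- function(model) {
  r <- .cbn_rho_cpp(model$n_genes, poset_parent_masks(model$poset),
                    model$lambda)
  data.frame(genotype = geno_string(r$masks, model$n_genes),
             mask = r$masks, prob = r$rho)
}

## Monotone nested parameter fit for a fixed poset: alternate an exact EM
## update of eps (posterior expected mismatch rate, holding lambda) with a
## guarded quasi-Newton improvement of lambda (holding eps). Updates are
## only accepted when they do not decrease the observed-data log-likelihood,
## so the trace is non-decreasing.
cbn_fit_params <- function(parent_masks, dc, lambda = NULL, eps = 0.05,
                           max_iter = 10L, lambda_only_iter = 25L,
                           tol = 1e-4) {
  K <- dc$K
  if (is.null(lambda)) {
    f <- pmin(pmax(vapply(seq_len(K), function(j) {
      sum(dc$counts[bitwAnd(dc$obs, bitwShiftL(1L, j - 1L)) > 0L])
    }, numeric(1)) / dc$n, 0.02), 0.98)
    lambda <- f / (1 - f)   # single-feature closed form P(mut) = l/(1+l)
  }
  eps <- min(max(eps, 1e-4), 0.45)
  ll <- .cbn_loglik_cpp(K, parent_masks, lambda, eps, dc$obs, dc$counts)
  trace <- ll
  for (it in seq_len(max_iter)) {
    ## lambda step
    obj <- function(lv) {
      -.cbn_loglik_cpp(K, parent_masks, exp(lv), eps, dc$obs, dc$counts)
    }
    opt <- stats::nlminb(log(lambda), obj,
                         lower = log(1e-4), upper = log(1e4),
                         control = list(iter.max = lambda_only_iter))
    if (-opt$objective >= ll) {
      lambda <- exp(opt$par)
      ll <- -opt$objective
    }
    ## eps step (EM update, guarded)
    eps_new <- .cbn_emismatch_cpp(K, parent_masks, lambda, eps,
                                  dc$obs, dc$counts)
    eps_new <- min(max(eps_new, 1e-6), 0.45)
    ll_new <- .cbn_loglik_cpp(K, parent_masks, lambda, eps_new,
                              dc$obs, dc$counts)
    if (ll_new >= ll) {
      eps <- eps_new
      ll <- ll_new
    }
    trace <- c(trace, ll)
    if (abs(trace[length(trace)] - trace[length(trace) - 1L]) < tol) break
  }
  list(lambda = lambda, eps = eps, loglik = ll, trace = trace)
}

#' Control parameters for the CBN annealing search
#'
#' @param restarts independent annealing restarts (best fit kept).
#' @param proposals poset proposals per restart.
#' @param t0 initial temperature; default `0.5 * sqrt(n)` at fit time.
#' @param t_end final temperature of the geometric cooling schedule.
#' @param search_iter inner parameter-fit iterations during the search
#'   (kept small; the best poset is refit fully at the end).
#' @param final_iter parameter-fit iterations for the final polish.
#' @param penalty `"none"` (pure maximum likelihood, the default) or
#'   `"bic"`.
#' @return list of class `cbn_control`.
#' @export
cbn_control <- function(restarts = 2L, proposals = 400L, t0 = NULL,
                        t_end = 0.1, search_iter = 2L, final_iter = 25L,
                        penalty = c("none", "bic")) {
  structure(list(restarts = restarts, proposals = proposals, t0 = t0,
                 t_end = t_end, search_iter = search_iter,
                 final_iter = final_iter, penalty = match.arg(penalty)),
            class = "cbn_control")
}

## poset moves on the edge matrix of direct relations
propose_poset_move <- function(edges, K) {
  i <- sample.int(K, 1L); j <- sample.int(K - 1L, 1L)
  if (j >= i) j <- j + 1L
  present <- nrow(edges) && any(edges[, 1] == i & edges[, 2] == j)
  if (present) {
    sel <- !(edges[, 1] == i & edges[, 2] == j)
    if (stats::runif(1) < 0.5) {
      edges[sel, , drop = FALSE]                       # delete
    } else {
      cand <- rbind(edges[sel, , drop = FALSE], c(j, i))  # swap
      if (is_acyclic(K, cand)) cand else edges[sel, , drop = FALSE]
    }
  } else {
    cand <- rbind(edges, c(i, j))                      # add cover relation
    if (is_acyclic(K, cand)) cand else edges
  }
}

edges_parent_masks <- function(edges, K) {
  pm <- integer(K)
  for (r in seq_len(nrow(edges)))
    pm[edges[r, 2]] <- bitwOr(pm[edges[r, 2]], bitwShiftL(1L, edges[r, 1] - 1L))
  pm
}

#' Fit a conjunctive Bayesian network
#'
#' Simulated annealing over posets of direct restrictions with a nested
#' monotone parameter fit (exact lattice likelihood); the best penalized
#' log-likelihood state visited across restarts is returned, refit fully.
#' With `proposals = 0` the fit of the empty poset is returned.
#'
#' Degenerate features (frequency 0 or 1) are excluded from the structure
#' search and re-attached as isolated nodes with clamped rates, with a
#' warning.
#'
#' @param dataset a `cpm_dataset` (K <= 14 features).
#' @param control a `cbn_control`.
#' @return a `cbn_model` with `loglik` attribute fields filled.
#' @export
fit_cbn <- function(dataset, control = cbn_control()) {
  stopifnot(inherits(dataset, "cpm_dataset"))
  K_all <- ncol(dataset$x)
  if (K_all > MAX_GENES) stop("at most ", MAX_GENES, " features supported")
  freq <- colMeans(dataset$x)
  degen <- freq <= 0 | freq >= 1
  if (any(degen)) {
    warning("features with degenerate frequency excluded from structure ",
            "search: ", paste(dataset$labels[degen], collapse = ", "))
    ds <- dataset
    ds$x <- dataset$x[, !degen, drop = FALSE]
    ds$labels <- dataset$labels[!degen]
    sub <- fit_cbn(ds, control)
    ## re-attach degenerate features as isolated nodes with clamped rates
    lam <- numeric(K_all)
    lam[!degen] <- sub$lambda
    lam[degen] <- ifelse(freq[degen] >= 1, 1e4, 1e-4)
    edges <- sub$poset$edges
    remap <- which(!degen)
    edges[] <- remap[edges]
    model <- cbn_model(new_poset(K_all, edges, dataset$labels), lam, sub$eps)
    model$loglik <- sub$loglik
    return(model)
  }
  dc <- dataset_counts(dataset)
  n_par <- function(edges) K_all + 1 + nrow(edges)
  pen <- function(fit, edges) {
    if (control$penalty == "bic")
      fit$loglik - n_par(edges) * log(dc$n) / 2
    else fit$loglik
  }
  empty <- matrix(integer(0), ncol = 2)
  fit0 <- cbn_fit_params(edges_parent_masks(empty, K_all), dc,
                         max_iter = control$final_iter)
  best <- list(edges = empty, fit = fit0, score = pen(fit0, empty))
  if (control$proposals > 0L) {
    t0 <- if (is.null(control$t0)) 0.5 * sqrt(dc$n) else control$t0
    alpha <- (control$t_end / t0)^(1 / max(1, control$proposals - 1))
    for (rs in seq_len(control$restarts)) {
      cur <- list(edges = empty, fit = fit0, score = pen(fit0, empty))
      temp <- t0
      for (pr in seq_len(control$proposals)) {
        cand_edges <- propose_poset_move(cur$edges, K_all)
        cand_fit <- cbn_fit_params(edges_parent_masks(cand_edges, K_all), dc,
                                   lambda = cur$fit$lambda,
                                   eps = cur$fit$eps,
                                   max_iter = control$search_iter,
                                   lambda_only_iter = 8L)
        cand_score <- pen(cand_fit, cand_edges)
        if (cand_score > cur$score ||
            stats::runif(1) < exp((cand_score - cur$score) / temp)) {
          cur <- list(edges = cand_edges, fit = cand_fit, score = cand_score)
          if (cand_score > best$score) best <- cur
        }
        temp <- temp * alpha
      }
    }
  }
  final <- cbn_fit_params(edges_parent_masks(best$edges, K_all), dc,
                          lambda = best$fit$lambda, eps = best$fit$eps,
                          max_iter = control$final_iter)
  model <- cbn_model(new_poset(K_all, best$edges, dataset$labels),
                     final$lambda, final$eps)
  model$loglik <- final$loglik
  model$trace <- final$trace
  model
}

#' Sample cross-sectional data from a CBN model
#'
#' For each subject, each feature's waiting time is an Exp(lambda_j) delay
#' after all its parents have occurred; the genotype collects the features
#' occurring before an Exp(1) observation time, and each bit is then flipped
#' with probability `eps`.
#'
#' @param model a `cbn_model`.
#' @param n number of subjects.
#' @return a `cpm_dataset`.
#' @export
generate_from_cbn <- function(model, n) {
  stopifnot(inherits(model, "cbn_model"), n >= 1)
  K <- model$n_genes
  pm <- poset_parent_masks(model$poset)
  ## topological order of features
  ord <- integer(0)
  left <- seq_len(K)
  placed <- 0L
  while (length(left)) {
    ready <- left[bitwAnd(pm[left], placed) == pm[left]]
    ord <- c(ord, ready)
    for (j in ready) placed <- bitwOr(placed, bitwShiftL(1L, j - 1L))
    left <- setdiff(left, ready)
  }
  x <- matrix(0L, n, K, dimnames = list(NULL, model$labels))
  for (s in seq_len(n)) {
    tobs <- stats::rexp(1, 1)
    tt <- rep(Inf, K)
    for (j in ord) {
      par <- mask_genes(pm[j], K)
      start <- if (length(par)) max(tt[par]) else 0
      tt[j] <- start + stats::rexp(1, model$lambda[j])
    }
    g <- as.integer(tt <= tobs)
    if (model$eps > 0) {
      flip <- stats::runif(K) < model$eps
      g[flip] <- 1L - g[flip]
    }
    x[s, ] <- g
  }
  structure(list(x = x, labels = model$labels,
                 provenance = list(source = "generate_from_cbn")),
            class = "cpm_dataset")
}

#' Wrap an external CPM fit as a model usable by the path modules
#'
#' Adapter for third-party CPM tools: takes the inferred DAG (and optional
#' rates) and returns a `cbn_model` (rates given) or the bare `cpm_poset`
#' (uniform path weighting downstream).
#'
#' @param poset a `cpm_poset` (the tool's inferred restrictions).
#' @param lambda optional per-feature rates.
#' @param eps optional error rate.
#' @return a `cbn_model` or `cpm_poset`.
#' @export
external_cpm_adapter <- function(poset, lambda = NULL, eps = 0) {
  stopifnot(inherits(poset, "cpm_poset"))
  if (is.null(lambda)) poset else cbn_model(poset, lambda, eps)
}

#' @export
print.cbn_model <- function(x, ...) {
  cat("CBN model over", x$n_genes, "features; eps =",
      signif(x$eps, 3), "\n")
  print(x$poset)
  cat("  lambda:", paste(signif(x$lambda, 3), collapse = ", "), "\n")
  invisible(x)
}
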