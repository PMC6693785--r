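## Performance and predictability statistics: path diversities (S_p, S_c),
## scaled Jensen-Shannon divergence, 1-recall / 1-precision, and the
## unequal-path-length comparison procedure.

#' Path diversity (Shannon entropy, natural log)
#'
#' `S = -sum p ln p` with `0 ln 0 = 0`. Applied to a LOD distribution this
#' is the true evolutionary unpredictability S_p; applied to a CPM path
#' distribution it is the inferred unpredictability S_c.
#'
#' @param dist a `path_distribution` (any non-negative probability vector
#'   summing to 1 works).
#' @return entropy in nats.
#' @export
path_entropy <- function(dist) {
  p <- as.numeric(dist)
  p <- p[p > 0]
  -sum(p * log(p))
}

## 0.5 * sum(p * log2(p / m)) with zero-probability terms dropped
half_kl2 <- function(p, m) {
  i <- p > 0
  0.5 * sum(p[i] * log2(p[i] / m[i]))
}

#' Scaled Jensen-Shannon divergence between two path distributions
#'
#' Computed over the union support with logarithms base 2, so the value lies
#' in \[0, 1\]: 0 for identical distributions, 1 for disjoint supports. This
#' is the plain (equal-length) comparison; use
#' [compare_path_distributions()] when path lengths differ.
#'
#' @param P,Q `path_distribution`s (named probability vectors).
#' @return JS divergence in \[0, 1\].
#' @export
js_divergence <- function(P, Q) {
  keys <- union(names(P), names(Q))
  p <- stats::setNames(rep(0, length(keys)), keys)
  q <- p
  p[names(P)] <- as.numeric(P)
  q[names(Q)] <- as.numeric(Q)
  m <- (p + q) / 2
  min(1, max(0, half_kl2(p, m) + half_kl2(q, m)))
}

path_prefix <- function(paths, k) {
  vapply(strsplit(paths, ">", fixed = TRUE), function(f) {
    paste(utils::head(f, k), collapse = ">")
  }, character(1))
}

## one comparison group: LOD paths of terminal length k against the CPM
## distribution of common length Kc; returns P/Q vectors (with the summed
## unmatched entries) and the group's 1-recall and 1-precision flows.
compare_group <- function(p, k, q, Kc) {
  lp <- names(p); lq <- names(q)
  if (k == Kc) {
    keys <- union(lp, lq)
    P <- stats::setNames(rep(0, length(keys) + 0L), keys)
    Q <- P
    P[lp] <- p; Q[lq] <- q
    return(list(P = P, Q = Q,
                recall_miss = sum(p[!(lp %in% lq)]),
                precision_miss = sum(q[!(lq %in% lp)])))
  }
  if (k < Kc) {
    ## LOD paths shorter: each is fully accounted for when it is the prefix
    ## of some CPM path; the CPM paths sharing that prefix are summed, a
    ## fraction (Kc - k)/Kc of their mass being unmatched tail
    pref <- path_prefix(lq, k)
    qstar <- tapply(q, pref, sum)
    matched <- lp %in% names(qstar)
    Pm <- p[matched]
    Qm <- as.numeric(qstar[lp[matched]]) * (k / Kc)
    q_un <- sum(as.numeric(qstar[lp[matched]])) * ((Kc - k) / Kc) +
      sum(qstar[!(names(qstar) %in% lp)])
    p_un <- sum(p[!matched])
    P <- c(Pm, lod_only = p_un, cpm_only = 0)
    Q <- c(Qm, lod_only = 0, cpm_only = q_un)
    names(P)[seq_len(sum(matched))] <- lp[matched]
    names(Q) <- names(P)
    return(list(P = P, Q = Q,
                recall_miss = p_un,
                precision_miss = q_un))
  }
  ## k > Kc: LOD paths longer; group them by their first Kc mutations.
  ## A group matching a CPM path is accounted for up to Kc, a fraction
  ## (k - Kc)/k of its mass being unmatched.
  pref <- path_prefix(lp, Kc)
  pstar <- tapply(p, pref, sum)
  matched <- names(pstar) %in% lq
  Pm <- as.numeric(pstar[matched]) * (Kc / k)
  Qm <- q[names(pstar)[matched]]
  p_un <- sum(as.numeric(pstar[matched])) * ((k - Kc) / k) +
    sum(pstar[!matched])
  q_un <- sum(q[!(lq %in% names(pstar)[matched])])
  P <- c(Pm, lod_only = p_un, cpm_only = 0)
  Q <- c(Qm, lod_only = 0, cpm_only = q_un)
  if (sum(matched)) names(P)[seq_len(sum(matched))] <- names(pstar)[matched]
  names(Q) <- names(P)
  list(P = P, Q = Q,
       recall_miss = p_un,
       precision_miss = q_un)
}

#' Compare a LOD path distribution with a CPM path distribution
#'
#' Handles unequal path lengths: LOD paths are grouped by the number of
#' mutations `k` of their final genotype; within each group prefix matching
#' against the (single-length `Kc`) CPM paths is applied with fractional
#' accounting of the unmatched tails, indistinguishable prefixes summed into
#' single entries. The per-group JS, 1-recall and 1-precision are combined
#' as a weighted sum with weights `w_k`, the LOD frequency of each terminal
#' length. When all lengths are equal the result coincides exactly with
#' [js_divergence()] and the plain recall/precision sums.
#'
#' @param lod_dist `path_distribution` of observed LODs (any lengths).
#' @param cpm_dist `path_distribution` from a CPM (all paths of one length).
#' @param renormalize if TRUE (default) the conditional LOD distribution at
#'   each terminal length is renormalized to sum to 1 before the per-group
#'   JS; if FALSE the raw probability flows are used.
#' @return object of class `cpm_comparison`: `js`, `one_minus_recall`
#'   (P(not-DAG | LOD)), `one_minus_precision` (P(not-LOD | DAG)), and the
#'   per-length weights `w_k`.
#' @export
compare_path_distributions <- function(lod_dist, cpm_dist,
                                       renormalize = TRUE) {
  if (!length(lod_dist) || !length(cpm_dist))
    stop("empty path distribution")
  Kc <- unique(path_lengths(names(cpm_dist)))
  if (length(Kc) != 1L)
    stop("CPM paths must all have the same length")
  ks <- path_lengths(names(lod_dist))
  p_all <- as.numeric(lod_dist)
  q <- stats::setNames(as.numeric(cpm_dist), names(cpm_dist))
  w_k <- tapply(p_all, ks, sum)
  js <- recall <- precision <- 0
  for (kc in names(w_k)) {
    k <- as.integer(kc)
    sel <- ks == k
    p <- stats::setNames(p_all[sel], names(lod_dist)[sel])
    wk <- as.numeric(w_k[kc])
    if (renormalize) {
      g <- compare_group(p / wk, k, q, Kc)
      m <- (g$P + g$Q) / 2
      js <- js + wk * (half_kl2(g$P, m) + half_kl2(g$Q, m))
      recall <- recall + wk * g$recall_miss
      precision <- precision + wk * g$precision_miss
    } else {
      g <- compare_group(p, k, q, Kc)
      m <- (g$P + g$Q) / 2
      js <- js + half_kl2(g$P, m) + half_kl2(g$Q, m)
      recall <- recall + g$recall_miss
      precision <- precision + wk * g$precision_miss
    }
  }
  structure(list(js = min(1, max(0, js)),
                 one_minus_recall = min(1, max(0, recall)),
                 one_minus_precision = min(1, max(0, precision)),
                 w_k = w_k),
            class = "cpm_comparison")
}

#' Is the most common LOD recovered by the CPM?
#'
#' Returns 1 iff a modal LOD path (ties resolved by counting recovery if any
#' modal path is matched) is included in some CPM path under the
#' unequal-length rule: two paths match when the shorter is a prefix of the
#' other (or they are identical).
#'
#' @param lod_dist `path_distribution` of observed LODs.
#' @param cpm_paths character vector of CPM paths.
#' @return 0 or 1.
#' @export
most_common_lod_recovered <- function(lod_dist, cpm_paths) {
  if (!length(lod_dist) || !length(cpm_paths)) stop("empty input")
  p <- as.numeric(lod_dist)
  modal <- names(lod_dist)[p == max(p)]
  match1 <- function(a, b) {
    ka <- path_lengths(a); kb <- path_lengths(b)
    if (ka <= kb) path_prefix(b, ka) == a else path_prefix(a, kb) == b
  }
  for (m in modal)
    for (cp in cpm_paths)
      if (match1(m, cp)) return(1L)
  0L
}

#' @export
print.cpm_comparison <- function(x, ...) {
  cat(sprintf("JS = %.4f; 1-recall = %.4f; 1-precision = %.4f\n",
              x$js, x$one_minus_recall, x$one_minus_precision))
  invisible(x)
}
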