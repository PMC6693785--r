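## Bootstrap reliability of inferred path distributions: the JS_o,b
## statistic (mean JS between the path distribution fitted on the original
## data and those fitted on case-resampled bootstrap replicates).

#' Default fitter/weighter pairs for [bootstrap_jsob()]
#'
#' @param control a `cbn_control` for the CBN fitter.
#' @return a function `dataset -> path_distribution`.
#' @export
cbn_path_fitter <- function(control = cbn_control()) {
  function(dataset) weight_paths_cbn(fit_cbn(dataset, control))
}

#' @rdname cbn_path_fitter
#' @export
ot_path_fitter <- function() {
  function(dataset) weight_paths_ot(fit_ot(dataset))
}

#' Bootstrap reliability of an inferred path distribution (JS_o,b)
#'
#' Fits the model on the original data, then on `B` case-resampled (with
#' replacement, subject level) data sets of the same size, and averages the
#' JS between the original and each bootstrap path distribution. Feature
#' thresholding, when requested, is applied once to the original data and
#' the retained features are reused for every replicate. A failing replicate
#' is recorded as missing and the mean is taken over completed replicates.
#'
#' @param dataset a `cpm_dataset`.
#' @param path_fitter function mapping a dataset to a `path_distribution`
#'   (e.g. [cbn_path_fitter()]); parameters are refit on every replicate.
#' @param B number of bootstrap replicates (the study uses 100).
#' @param threshold optional feature-count threshold (7, 10 or 12 in the
#'   study) applied via [top_features()] before fitting.
#' @return object of class `reliability_result`: `js_ob`, `per_replicate`,
#'   `B`, `n_failed`, `s_c` (diversity of the original fit's paths).
#' @export
bootstrap_jsob <- function(dataset, path_fitter = cbn_path_fitter(),
                           B = 100L, threshold = NULL) {
  stopifnot(inherits(dataset, "cpm_dataset"), B >= 1)
  if (!is.null(threshold)) dataset <- top_features(dataset, threshold)
  orig <- path_fitter(dataset)
  n <- nrow(dataset$x)
  per <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    ds <- dataset
    ds$x <- dataset$x[sample.int(n, n, replace = TRUE), , drop = FALSE]
    bd <- tryCatch(path_fitter(ds), error = function(e) NULL)
    if (!is.null(bd))
      per[b] <- compare_path_distributions(bd, orig)$js
  }
  structure(list(js_ob = mean(per, na.rm = TRUE), per_replicate = per,
                 B = B, n_failed = sum(is.na(per)),
                 s_c = path_entropy(orig)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("JS_o,b = %.4f over %d bootstrap replicates (%d failed); ",
              x$js_ob, x$B, x$n_failed),
      sprintf("original-fit S_c = %.3f\n", x$s_c))
  invisible(x)
}
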