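#' Remove constant descriptor columns
#'
#' Descriptors that do not vary across the compounds carry no information for
#' regression and make the design singular; columns whose sample standard
#' deviation is at most `tol` are removed. Survivor order is preserved.
#'
#' @param x numeric descriptor matrix (compounds x descriptors).
#' @param tol non-negative absolute tolerance on the sample standard
#'   deviation; default `1e-12`.
#' @return A list with `descriptors` (the pruned matrix) and `report`
#'   (a `prune_report`).
#' @export
drop_constant <- function(x, tol = 1e-12) {
  x <- as_descriptor_matrix(x)
  if (!is_scalar_number(tol) || tol < 0) {
    stop_ermqsar("`tol` must be a non-negative number", "ermqsar_config_error")
  }
  sds <- apply(x, 2L, stats::sd)
  constant <- sds <= tol
  if (all(constant)) {
    stop_ermqsar("empty pool: every descriptor column is constant",
                 "ermqsar_empty_pool_error")
  }
  out <- x[, !constant, drop = FALSE]
  report <- prune_report(removed_constant = colnames(x)[constant],
                         removed_correlated = list(), threshold = NA_real_,
                         n_remaining = ncol(out))
  list(descriptors = out, report = report)
}

#' Remove intercorrelated descriptor columns
#'
#' Pairs of descriptors whose absolute Pearson correlation exceeds
#' `threshold` are redundant; one of each pair is deleted. The scan is a
#' deterministic greedy left-to-right pass: for each surviving column in
#' input order, every later column correlated with it beyond the threshold is
#' dropped. After the pass no surviving pair has |r| > threshold, and
#' re-applying the filter changes nothing.
#'
#' The comparison is on |r| (a descriptor anti-correlated at -0.9 is as
#' redundant as one correlated at +0.9) and strict: a pair at exactly the
#' threshold is kept. Constant columns must be removed first (see
#' [drop_constant()]); their correlations are undefined.
#'
#' @param x numeric descriptor matrix with at least 2 rows and no constant
#'   columns.
#' @param threshold correlation threshold in (0, 1); default 0.75.
#' @return A list with `descriptors` and `report`; the report records each
#'   (kept, dropped, r) triple with the signed correlation.
#' @export
correlation_prune <- function(x, threshold = 0.75) {
  x <- as_descriptor_matrix(x)
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1) {
    stop_ermqsar("`threshold` must lie strictly between 0 and 1",
                 "ermqsar_config_error")
  }
  if (nrow(x) < 2L) {
    stop_ermqsar("need at least 2 compounds to compute correlations",
                 "ermqsar_validation_error")
  }
  cm <- suppressWarnings(stats::cor(x))
  if (any(!is.finite(cm))) {
    stop_ermqsar("undefined correlations (constant column?): run drop_constant() first",
                 "ermqsar_validation_error")
  }
  D <- ncol(x)
  keep <- rep(TRUE, D)
  pairs <- list()
  for (j in seq_len(D)) {
    if (!keep[j]) next
    later <- which(keep & seq_len(D) > j & abs(cm[j, ]) > threshold)
    for (k in later) {
      keep[k] <- FALSE
      pairs[[length(pairs) + 1L]] <- list(kept = colnames(x)[j],
                                          dropped = colnames(x)[k],
                                          r = unname(cm[j, k]))
    }
  }
  out <- x[, keep, drop = FALSE]
  if (ncol(out) == 0L) {
    stop_ermqsar("empty pool after correlation pruning", "ermqsar_empty_pool_error")
  }
  report <- prune_report(removed_constant = character(0),
                         removed_correlated = pairs, threshold = threshold,
                         n_remaining = ncol(out))
  list(descriptors = out, report = report)
}

#' Prune a raw descriptor pool
#'
#' Convenience wrapper running [drop_constant()] then [correlation_prune()],
#' merging the two reports.
#'
#' @inheritParams drop_constant
#' @inheritParams correlation_prune
#' @return A list with `descriptors` and a merged `report`.
#' @export
prune_descriptors <- function(x, threshold = 0.75, tol = 1e-12) {
  s1 <- drop_constant(x, tol = tol)
  s2 <- correlation_prune(s1$descriptors, threshold = threshold)
  report <- prune_report(removed_constant = s1$report$removed_constant,
                         removed_correlated = s2$report$removed_correlated,
                         threshold = threshold,
                         n_remaining = ncol(s2$descriptors))
  list(descriptors = s2$descriptors, report = report)
}

prune_report <- function(removed_constant, removed_correlated, threshold,
                         n_remaining) {
  structure(list(removed_constant = as.character(removed_constant),
                 removed_correlated = removed_correlated,
                 threshold = threshold, n_remaining = n_remaining),
            class = "prune_report")
}

#' @export
print.prune_report <- function(x, ...) {
  cat(sprintf("Descriptor prune report: %d constant removed, %d dropped as intercorrelated (|r| > %s), %d remaining\n",
              length(x$removed_constant), length(x$removed_correlated),
              format(x$threshold), x$n_remaining))
  invisible(x)
}

# JSON-friendly form used by the pipeline audit log
prune_report_as_list <- function(x) {
  list(
    removed_constant = x$removed_constant,
    removed_correlated = lapply(x$removed_correlated, function(p)
      list(kept = p$kept, dropped = p$dropped, r = p$r)),
    threshold = x$threshold,
    n_remaining = x$n_remaining
  )
}
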