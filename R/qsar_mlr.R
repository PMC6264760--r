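#' Fit a QSAR model by descriptor-subset selection
#'
#' The package's main entry point: prunes the descriptor pool (constant
#' columns, then intercorrelated pairs), selects a size-`d` descriptor
#' subset on the training split by minimising the regression SD (Enhanced
#' Replacement Method by default), fits the final OLS model and validates it
#' by leave-one-out cross-validation and, when a test split exists, external
#' test-set correlation.
#'
#' @param descriptors compounds-by-descriptors numeric matrix (or data frame
#'   with a `compound_id` first column), or an existing [qsar_dataset()]
#'   (then `activities` is ignored).
#' @param activities activity table acceptable to [activity_records()].
#' @param d subset size; default is the overfitting cap
#'   [max_subset_size()] of the training split. May be a vector, in which
#'   case every size is scanned and the one with the best Q2_loo is kept
#'   (see [select_model_size()]).
#' @param method search method: `"erm"` (default), `"rm"` or `"fs"`.
#' @param seed integer seed for the randomly initialised searches. With
#'   `restarts > 1`, runs use seeds `seed, seed + 1, ...` and the
#'   lowest-SD result is kept.
#' @param restarts number of independent search restarts (default 1).
#' @param prune run [prune_descriptors()] first (default `TRUE`).
#' @param threshold correlation-filter threshold (default 0.75).
#' @param constant_tol constant-column SD tolerance (default 1e-12).
#' @param response response column name (default `"pec50"`).
#' @return An object of class `qsar_mlr`: list with `model` (a `qsar_lm`),
#'   `selection`, `validation`, `prune_report`, `size_scan` (when `d` was a
#'   range), `dataset` (the pruned dataset) and `call`. Supports `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot` and
#'   `simulate`.
#' @examples
#' pool <- generate_pool(synthetic_spec(
#'   n_compounds = 30, pool_size = 15, true_subset_size = 2,
#'   true_coefficients = c(1, -1), noise_sd = 0.2, seed = 7))
#' fit <- qsar_mlr(pool$dataset, d = 2, seed = 7)
#' fit
#' @export
qsar_mlr <- function(descriptors, activities = NULL, d = NULL,
                     method = c("erm", "rm", "fs"), seed = 1L, restarts = 1L,
                     prune = TRUE, threshold = 0.75, constant_tol = 1e-12,
                     response = "pec50") {
  method <- match.arg(method)
  dataset <- if (inherits(descriptors, "qsar_dataset")) descriptors
             else qsar_dataset(descriptors, activities, response_name = response)
  prune_rep <- NULL
  if (prune) {
    pruned <- prune_descriptors(dataset$descriptors, threshold = threshold,
                                tol = constant_tol)
    prune_rep <- pruned$report
    dataset <- qsar_dataset(pruned$descriptors, dataset$activities,
                            response_name = dataset$response_name)
  }
  n_tr <- length(train_index(dataset))
  cap <- max_subset_size(n_tr)
  if (is.null(d)) d <- cap
  d <- as.integer(d)

  size_scan <- NULL
  if (length(d) > 1L) {
    size_scan <- select_model_size(dataset, d, seed = seed)
    best <- size_scan$results[[as.character(size_scan$best_d)]]
    selection <- best$selection
    validation <- best$validation
  } else {
    if (d > cap) {
      stop_ermqsar(sprintf("d = %d exceeds the 20%% overfitting cap of %d for %d training compounds",
                           d, cap, n_tr), "ermqsar_config_error")
    }
    selection <- select_descriptors(dataset, d, method = method, seed = seed)
    if (restarts > 1L && method != "fs") {
      for (r in seq_len(restarts - 1L)) {
        cand <- select_descriptors(dataset, d, method = method, seed = seed + r)
        if (cand$model$sd < selection$model$sd) selection <- cand
      }
    }
    validation <- validation_report(dataset, selection$subset)
  }
  structure(list(model = selection$model, selection = selection,
                 validation = validation, prune_report = prune_rep,
                 size_scan = size_scan, dataset = dataset,
                 call = match.call()),
            class = "qsar_mlr")
}

#' @export
print.qsar_mlr <- function(x, ...) {
  cat(sprintf("QSAR model (%s selection, seed %s)\n",
              x$selection$method,
              if (is.na(x$selection$seed)) "-" else x$selection$seed))
  cat(" ", render_equation(x$model), "\n")
  cat(sprintf("  N = %d, d = %d: R2 = %.3f, SD = %.3f, F = %.3g; Q2_loo = %.3f%s\n",
              x$model$n_train, length(x$model$subset), x$model$r2, x$model$sd,
              x$model$f_stat, x$validation$q2_loo,
              if (!is.null(x$validation$r2_test))
                sprintf(", R2_test = %.3f", x$validation$r2_test) else ""))
  invisible(x)
}

#' @export
summary.qsar_mlr <- function(object, ...) {
  structure(list(fit = object,
                 coefficients = summary(object$model)$coefficients,
                 comparison = if (!is.null(object$size_scan))
                   object$size_scan$comparison),
            class = "summary.qsar_mlr")
}

#' @export
print.summary.qsar_mlr <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  print(x$coefficients, digits = 4)
  if (!is.null(x$fit$prune_report)) print(x$fit$prune_report)
  if (!is.null(x$comparison)) {
    cat("\nModel-size scan:\n")
    print(x$comparison, row.names = FALSE)
  }
  cat("\nLeave-one-out:", sprintf("Q2 = %.3f, SD(cv) = %.3f\n",
                                  x$fit$validation$q2_loo, x$fit$validation$sd_cv))
  invisible(x)
}

#' @export
coef.qsar_mlr <- function(object, ...) coef(object$model)

#' @export
fitted.qsar_mlr <- function(object, ...) fitted(object$model)

#' @export
residuals.qsar_mlr <- function(object, ...) residuals(object$model)

#' @export
predict.qsar_mlr <- function(object, newdata, ...) {
  if (missing(newdata)) {
    return(predict(object$model, object$dataset$descriptors))
  }
  predict(object$model, newdata, ...)
}

#' Observed-versus-predicted plot of a QSAR fit
#'
#' @param x a `qsar_mlr`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.qsar_mlr <- function(x, ...) {
  p <- x$validation$predictions
  is_test <- p$split == "test"
  graphics::plot(p$observed, p$predicted,
                 pch = ifelse(is_test, 17, 16),
                 col = ifelse(is_test, "firebrick", "steelblue"),
                 xlab = sprintf("Observed %s", x$dataset$response_name),
                 ylab = sprintf("Predicted %s", x$dataset$response_name), ...)
  graphics::abline(0, 1, lty = 2)
  if (any(is_test)) {
    graphics::legend("topleft", legend = c("train", "test"), pch = c(16, 17),
                     col = c("steelblue", "firebrick"), bty = "n")
  }
  invisible(x)
}

#' Simulate responses from a fitted QSAR model
#'
#' Draws Gaussian responses around the model's fitted training values with
#' the model's residual SD.
#'
#' @param object a `qsar_mlr`.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param ... unused.
#' @return Data frame with `nsim` columns, one row per training compound.
#' @export
simulate.qsar_mlr <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object$model)
  draw <- function() mu + stats::rnorm(length(mu), 0, object$model$sd)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  sims <- as.data.frame(sims)
  names(sims) <- paste0("sim_", seq_len(nsim))
  rownames(sims) <- names(mu)
  sims
}
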