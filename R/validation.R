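#' Leave-one-out cross-validation of a descriptor subset
#'
#' Each training compound is held out in turn, the model is refitted on the
#' remaining `n - 1` compounds and the held-out response predicted; the loop
#' is the literal n-refit procedure, not a shortcut. Summaries:
#' `Q2 = 1 - PRESS / TSS` with TSS taken about the full training-set mean,
#' and `sd_cv = sqrt(PRESS / (n - d - 1))`.
#'
#' @param dataset a [qsar_dataset()].
#' @param subset character vector of descriptor names.
#' @return An object of class `qsar_validation`: `q2_loo`, `sd_cv`, `press`,
#'   and `per_compound` (one row per training compound: observed, predicted,
#'   residual).
#' @export
loo_cv <- function(dataset, subset) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  subset <- as.character(subset)
  d <- length(subset)
  tr <- train_index(dataset)
  n <- length(tr)
  if (n < d + 3L) {
    stop_ermqsar(sprintf("LOO needs at least d + 3 = %d training compounds, have %d",
                         d + 3L, n), "ermqsar_domain_error")
  }
  X <- dataset$descriptors[tr, subset, drop = FALSE]
  y <- response_vector(dataset)[tr]
  ids <- dataset$activities$compound_id[tr]
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- ols_core(X[-i, , drop = FALSE], y[-i])
    if (is.null(fit)) {
      stop_ermqsar(sprintf("singular LOO fold when leaving out compound '%s'", ids[i]),
                   "ermqsar_singular_fit")
    }
    pred[i] <- fit$coefficients[1L] + sum(fit$coefficients[-1L] * X[i, ])
  }
  press <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) {
    stop_ermqsar("response has zero variance on the training set", "ermqsar_domain_error")
  }
  structure(list(
    q2_loo = 1 - press / tss,
    sd_cv = sqrt(press / (n - d - 1L)),
    press = press,
    per_compound = data.frame(compound_id = ids, observed = y, predicted = pred,
                              residual = y - pred, stringsAsFactors = FALSE)
  ), class = "qsar_validation")
}

#' @export
print.qsar_validation <- function(x, ...) {
  cat(sprintf("Leave-one-out: Q2 = %.3f, SD(cv) = %.3f over %d compounds\n",
              x$q2_loo, x$sd_cv, nrow(x$per_compound)))
  invisible(x)
}

#' External test-set correlation
#'
#' Squared Pearson correlation between observed and model-predicted
#' responses on held-out compounds. Being correlation-based it is invariant
#' to affine shifts of either vector (a systematically biased but perfectly
#' rank-preserving predictor still scores 1); the stricter predictive-R2
#' about the training mean is available via `predictive = TRUE`.
#'
#' @param model a `qsar_lm`.
#' @param descriptors matrix/data frame of test-row descriptor values
#'   containing the model's subset columns (at least 3 rows).
#' @param observed numeric vector of observed responses, one per row.
#' @param predictive if `TRUE` return `1 - sum((obs - pred)^2) /
#'   sum((obs - train_mean)^2)` instead, with `train_mean` taken from
#'   `mean(fitted(model))`.
#' @return Scalar in \[0, 1\] (predictive form can be negative).
#' @export
test_set_r2 <- function(model, descriptors, observed, predictive = FALSE) {
  stopifnot(inherits(model, "qsar_lm"))
  pred <- predict(model, descriptors)
  if (length(observed) != length(pred) || length(observed) < 3L) {
    stop_ermqsar("need at least 3 test compounds with observed responses",
                 "ermqsar_domain_error")
  }
  if (predictive) {
    if (is.null(model$fitted)) {
      stop_ermqsar("predictive R2 needs a model fitted in-package (training mean unknown)",
                   "ermqsar_domain_error")
    }
    ybar <- mean(model$fitted)
    return(1 - sum((observed - pred)^2) / sum((observed - ybar)^2))
  }
  if (stats::sd(observed) == 0 || stats::sd(pred) == 0) {
    stop_ermqsar("correlation undefined: zero variance in observed or predicted values",
                 "ermqsar_undefined_correlation")
  }
  stats::cor(observed, pred)^2
}

#' Maximum admissible descriptor-subset size
#'
#' To guard against overfitting, the number of selected descriptors is kept
#' strictly below `fraction` (default 20%) of the training-set size: the
#' returned cap is the largest integer strictly less than
#' `fraction * n_train`. At exact integer multiples the cap therefore rounds
#' down by one (25 compounds -> 4, not 5).
#'
#' @param n_train training-set size (>= 5).
#' @param fraction upper fraction, default 0.2.
#' @return Integer cap >= 1.
#' @export
max_subset_size <- function(n_train, fraction = 0.2) {
  if (!is_scalar_number(n_train) || n_train < 5 || n_train != round(n_train)) {
    stop_ermqsar("`n_train` must be an integer >= 5", "ermqsar_domain_error")
  }
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction >= 1) {
    stop_ermqsar("`fraction` must lie in (0, 1)", "ermqsar_config_error")
  }
  f <- fraction * n_train
  cap <- if (abs(f - round(f)) < 1e-9) round(f) - 1L else floor(f)
  if (cap < 1L) {
    stop_ermqsar(sprintf("training set of %d admits no model under the %.0f%% cap",
                         n_train, 100 * fraction), "ermqsar_domain_error")
  }
  as.integer(cap)
}

#' Full validation of a descriptor subset
#'
#' Fits the subset on the training rows, runs [loo_cv()] and, when the
#' dataset has at least 3 test compounds, [test_set_r2()]; collects
#' per-compound predictions for both splits.
#'
#' @inheritParams loo_cv
#' @return A `qsar_validation` additionally carrying `r2_test` (or `NULL`),
#'   `model`, and a `predictions` table over all compounds (observed,
#'   predicted, residual, split).
#' @export
validation_report <- function(dataset, subset) {
  model <- fit_ols(dataset, subset)
  val <- loo_cv(dataset, subset)
  te <- test_index(dataset)
  val$model <- model
  val$r2_test <- NULL
  if (length(te) >= 3L) {
    Xte <- dataset$descriptors[te, , drop = FALSE]
    obs <- response_vector(dataset)[te]
    val$r2_test <- tryCatch(test_set_r2(model, Xte, obs),
                            ermqsar_undefined_correlation = function(e) NULL)
  }
  all_pred <- predict(model, dataset$descriptors)
  y <- response_vector(dataset)
  val$predictions <- data.frame(
    compound_id = dataset$activities$compound_id,
    observed = y, predicted = all_pred, residual = y - all_pred,
    split = dataset$activities$split, stringsAsFactors = FALSE
  )
  val
}
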