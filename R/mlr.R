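# Fast internal OLS on an explicit design (intercept prepended). Returns NULL
# on rank deficiency so subset searches can treat singular candidates as
# inadmissible rather than crash.
ols_core <- function(X, y) {
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xd, y)
  p <- ncol(Xd)
  if (fit$rank < p) return(NULL)
  res <- fit$residuals
  rss <- sum(res * res)
  list(coefficients = fit$coefficients, residuals = res,
       fitted = y - res, rss = rss, qr = fit$qr, p = p)
}

# residual SD of each candidate subset: the search objective. NA if singular.
subset_sd <- function(X, y, idx) {
  d <- length(idx)
  fit <- ols_core(X[, idx, drop = FALSE], y)
  if (is.null(fit)) return(NA_real_)
  sqrt(fit$rss / (length(y) - d - 1L))
}

# coefficient standard errors from a full-rank lm.fit QR (pivot-aware)
ols_se <- function(fit, sigma2) {
  p <- fit$p
  R <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  piv <- fit$qr$pivot[seq_len(p)]
  se <- numeric(p)
  se[piv] <- sqrt(diag(chol2inv(R)) * sigma2)
  names(se) <- names(fit$coefficients)
  se
}

#' Residual standard deviation of a fit
#'
#' The objective minimised by the subset searches:
#' `SD = sqrt(sum(res_i^2) / (n - d - 1))`, the residual standard deviation
#' with `n - d - 1` degrees of freedom (d descriptors plus an intercept).
#'
#' @param residuals numeric vector of length `n`.
#' @param n number of training compounds.
#' @param d number of descriptors in the model.
#' @return Non-negative scalar.
#' @export
sd_of_fit <- function(residuals, n, d) {
  if (!is_scalar_number(n) || !is_scalar_number(d) || n <= d + 1) {
    stop_ermqsar("need n > d + 1 residual degrees of freedom", "ermqsar_domain_error")
  }
  if (length(residuals) != n) {
    stop_ermqsar("`residuals` must have length n", "ermqsar_domain_error")
  }
  sqrt(sum(residuals^2) / (n - d - 1))
}

#' Overall regression F statistic
#'
#' Standard overall-significance F for an OLS model with `d` regressors and
#' an intercept: `(r2/d) / ((1 - r2)/(n - d - 1))`. A perfect fit
#' (`r2 == 1`) returns `Inf`.
#'
#' @param r2 coefficient of determination in \[0, 1\].
#' @param n training-set size.
#' @param d number of descriptors.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
f_statistic <- function(r2, n, d) {
  if (!is_scalar_number(r2) || r2 < 0 || r2 > 1) {
    stop_ermqsar("`r2` must lie in [0, 1]", "ermqsar_domain_error")
  }
  if (!is_scalar_number(n) || !is_scalar_number(d) || n <= d + 1) {
    stop_ermqsar("need n > d + 1", "ermqsar_domain_error")
  }
  if (r2 == 1) return(Inf)
  (r2 / d) / ((1 - r2) / (n - d - 1))
}

#' Fit an OLS model on a descriptor subset
#'
#' Ordinary least squares of the dataset's response on the named descriptor
#' subset plus an intercept, using the training rows only. Descriptors enter
#' on their raw scale. A rank-deficient design raises a singular-fit error
#' (condition class `ermqsar_singular_fit`) so that subset searches can treat
#' the subset as inadmissible.
#'
#' @param dataset a [qsar_dataset()].
#' @param subset character vector of descriptor names (size `d >= 1`).
#' @return An object of class `qsar_lm`: subset, named `coefficients`,
#'   `intercept`, `n_train`, fit statistics `r2`, `sd`
#'   (residual SD on `n - d - 1` df), `f_stat`, `coefficient_se`, plus
#'   training `residuals` and `fitted` values.
#' @export
fit_ols <- function(dataset, subset) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  subset <- as.character(subset)
  d <- length(subset)
  if (d < 1L) stop_ermqsar("subset must contain at least one descriptor",
                           "ermqsar_domain_error")
  missing <- setdiff(subset, colnames(dataset$descriptors))
  if (length(missing)) {
    stop_ermqsar(sprintf("unknown descriptor(s): %s", paste(missing, collapse = ", ")),
                 "ermqsar_domain_error")
  }
  tr <- train_index(dataset)
  n <- length(tr)
  if (n < d + 2L) {
    stop_ermqsar(sprintf("need at least d + 2 = %d training compounds, have %d",
                         d + 2L, n), "ermqsar_domain_error")
  }
  X <- dataset$descriptors[tr, subset, drop = FALSE]
  y <- response_vector(dataset)[tr]
  fit <- ols_core(X, y)
  if (is.null(fit)) {
    stop_ermqsar(sprintf("singular fit for subset {%s}", paste(subset, collapse = ", ")),
                 "ermqsar_singular_fit")
  }
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - fit$rss / tss)) else 0
  sdfit <- sqrt(fit$rss / (n - d - 1L))
  se <- ols_se(fit, sdfit^2)
  new_qsar_lm(
    subset = subset,
    coefficients = stats::setNames(fit$coefficients[-1L], subset),
    intercept = unname(fit$coefficients[1L]),
    n_train = n, r2 = r2, sd = sdfit, f_stat = f_statistic(r2, n, d),
    coefficient_se = stats::setNames(se[-1L], subset),
    intercept_se = unname(se[1L]),
    residuals = stats::setNames(fit$residuals, rownames(X)),
    fitted = stats::setNames(fit$fitted, rownames(X)),
    response_name = dataset$response_name,
    source = "fitted"
  )
}

new_qsar_lm <- function(...) {
  structure(list(...), class = "qsar_lm")
}

#' The published five-descriptor vasorelaxant activity model
#'
#' The benchmark QSAR equation for flavonoid vasorelaxant potency,
#' reconstructed verbatim from its published coefficients:
#'
#' `-Log(EC50) = 0.442*H5m - 0.465*SIC2 + 0.287*DISPe - 0.518*Mor03u - 0.574*L3m + 4.376`
#'
#' The descriptors are a GETAWAY autocorrelation (H5m), an information index
#' (SIC2), a geometrical descriptor (DISPe), a 3D-MoRSE signal (Mor03u) and a
#' WHIM size index (L3m). The attached fit statistics (R2 = 0.839,
#' SD = 0.263, F = 21.9, n = 26) are the published figures stored as
#' metadata; they cannot be recomputed because the underlying descriptor
#' values were never published.
#'
#' @return A `qsar_lm` whose `source` field is `"published"`.
#' @examples
#' m <- eq1_model()
#' predict(m, c(0, 0, 0, 0, 0))  # the intercept, 4.376
#' @export
eq1_model <- function() {
  subset <- c("H5m", "SIC2", "DISPe", "Mor03u", "L3m")
  new_qsar_lm(
    subset = subset,
    coefficients = stats::setNames(c(0.442, -0.465, 0.287, -0.518, -0.574), subset),
    intercept = 4.376,
    n_train = 26L, r2 = 0.839, sd = 0.263, f_stat = 21.9,
    coefficient_se = stats::setNames(rep(NA_real_, 5L), subset),
    intercept_se = NA_real_,
    residuals = NULL, fitted = NULL,
    response_name = "-Log(EC50)",
    source = "published"
  )
}

#' @export
coef.qsar_lm <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
residuals.qsar_lm <- function(object, ...) object$residuals

#' @export
fitted.qsar_lm <- function(object, ...) object$fitted

#' Predict from a fitted descriptor-subset model
#'
#' @param object a `qsar_lm`.
#' @param newdata either a numeric vector of length `d` aligned to
#'   `object$subset`, or a matrix/data frame containing columns named after
#'   the subset.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.qsar_lm <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  d <- length(object$subset)
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (length(newdata) != d) {
      stop_ermqsar(sprintf("descriptor vector must have length %d", d),
                   "ermqsar_domain_error")
    }
    if (any(!is.finite(newdata))) {
      stop_ermqsar("descriptor values must be finite", "ermqsar_domain_error")
    }
    return(object$intercept + sum(object$coefficients * newdata))
  }
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  missing_cols <- setdiff(object$subset, colnames(newdata))
  if (length(missing_cols)) {
    stop_ermqsar(sprintf("newdata lacks descriptor(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "ermqsar_domain_error")
  }
  drop(newdata[, object$subset, drop = FALSE] %*% object$coefficients) +
    object$intercept
}

#' Render a model as its one-line equation
#'
#' Deterministic plain-text rendering in the conventional QSAR form:
#' response name, then signed 3-decimal coefficients times descriptor names
#' in subset order, then the signed intercept, e.g.
#' `"-Log(EC50) = 0.442*H5m - 0.465*SIC2 + ... + 4.376"`.
#'
#' @param model a `qsar_lm`.
#' @return A single string.
#' @export
render_equation <- function(model) {
  stopifnot(inherits(model, "qsar_lm"))
  # signs decided on the rounded values so that -1e-17 renders as "+ 0.000"
  cs <- round(model$coefficients, 3)
  ic <- round(model$intercept, 3)
  fmt <- function(v) formatC(abs(v), format = "f", digits = 3)
  terms <- sprintf("%s*%s", fmt(cs), model$subset)
  first <- paste0(if (cs[1L] < 0) "-" else "", terms[1L])
  rest <- if (length(terms) > 1L) {
    paste0(ifelse(cs[-1L] < 0, " - ", " + "), terms[-1L], collapse = "")
  } else ""
  icpt <- paste0(if (ic < 0) " - " else " + ", fmt(ic))
  paste0(model$response_name, " = ", first, rest, icpt)
}

#' @export
print.qsar_lm <- function(x, ...) {
  cat(render_equation(x), "\n")
  cat(sprintf("d = %d descriptors, N = %d; R2 = %.3f, SD = %.3f, F = %.3g%s\n",
              length(x$subset), x$n_train, x$r2, x$sd, x$f_stat,
              if (identical(x$source, "published")) " (published figures)" else ""))
  invisible(x)
}

#' @export
summary.qsar_lm <- function(object, ...) {
  tab <- data.frame(
    estimate = coef(object),
    std_error = c(object$intercept_se, object$coefficient_se),
    row.names = c("(Intercept)", object$subset)
  )
  structure(list(model = object, coefficients = tab), class = "summary.qsar_lm")
}

#' @export
print.summary.qsar_lm <- function(x, ...) {
  print(x$model)
  cat("\nCoefficients:\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

# JSON-friendly serialisation; full-precision coefficients
model_as_list <- function(model) {
  list(
    subset = model$subset,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    n_train = model$n_train,
    d = length(model$subset),
    r2 = model$r2, sd = model$sd, f_stat = model$f_stat,
    coefficient_se = as.list(model$coefficient_se),
    equation = render_equation(model),
    source = model$source
  )
}
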