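#' Convert an EC50 in micromolar to pEC50
#'
#' The modelled response throughout this package is the negative base-10
#' logarithm of the molar half-maximal effective concentration,
#' pEC50 = -log10(EC50 \[M\]). Input concentrations are in micromolar, the
#' unit in which vasorelaxant potencies are conventionally tabulated, so the
#' transformation is `-log10(ec50 * 1e-6)`.
#'
#' @param ec50 numeric vector of EC50 values in micromolar; all elements must
#'   be finite and strictly positive.
#' @return Numeric vector of pEC50 values (unitless, -log10 molar). The map is
#'   a strictly decreasing bijection from (0, Inf) micromolar to the reals.
#' @seealso [ec50_from_pec50()] for the inverse.
#' @examples
#' pec50_from_ec50(7.6)   # 5.119
#' pec50_from_ec50(1e6)   # 1 M -> 0
#' @export
pec50_from_ec50 <- function(ec50) {
  if (!is.numeric(ec50) || length(ec50) == 0L) {
    stop_ermqsar("`ec50` must be a non-empty numeric vector", "ermqsar_domain_error")
  }
  if (any(!is.finite(ec50)) || any(ec50 <= 0)) {
    stop_ermqsar("`ec50` must be finite and strictly positive (micromolar)",
                 "ermqsar_domain_error")
  }
  -log10(ec50 * 1e-6)
}

#' Convert a pEC50 back to an EC50 in micromolar
#'
#' Inverse of [pec50_from_ec50()]: `10^(-pec50) * 1e6`.
#'
#' @param pec50 numeric vector, finite.
#' @return EC50 in micromolar.
#' @export
ec50_from_pec50 <- function(pec50) {
  if (!is.numeric(pec50) || any(!is.finite(pec50))) {
    stop_ermqsar("`pec50` must be finite numeric", "ermqsar_domain_error")
  }
  10^(-pec50) * 1e6
}

#' Residual of a predicted activity
#'
#' Residual = experimental minus predicted, the convention used when
#' tabulating QSAR predictions.
#'
#' @param experimental,predicted finite numeric vectors (recycled).
#' @return `experimental - predicted`.
#' @export
activity_residual <- function(experimental, predicted) {
  if (any(!is.finite(experimental)) || any(!is.finite(predicted))) {
    stop_ermqsar("inputs must be finite", "ermqsar_domain_error")
  }
  experimental - predicted
}

# Tolerance for flagging a printed pEC50 as inconsistent with its EC50.
PEC50_CONSISTENCY_TOL <- 0.01

#' Assemble and validate a table of activity records
#'
#' Normalises a data frame of per-compound activity records: checks split
#' labels, positivity of EC50, derives pEC50 from EC50 where absent, and flags
#' rows whose stated pEC50 disagrees with their EC50 by more than 0.01 log
#' units (such rows are kept as given, never silently corrected).
#'
#' @param df data frame with columns `compound_id` and at least one of
#'   `ec50_uM`, `pec50`; optional `emax_pct`, `split`, `predicted`, `residual`.
#' @return A data frame of class `activity_table` with columns `compound_id`,
#'   `ec50_uM`, `pec50`, `emax_pct`, `split`, `predicted`, `residual`,
#'   `inconsistent` (logical).
#' @export
activity_records <- function(df) {
  if (!is.data.frame(df) || !"compound_id" %in% names(df)) {
    stop_ermqsar("`df` must be a data frame with a `compound_id` column",
                 "ermqsar_validation_error")
  }
  id <- as.character(df$compound_id)
  if (anyDuplicated(id)) {
    stop_ermqsar(sprintf("duplicate compound_id: %s",
                         paste(unique(id[duplicated(id)]), collapse = ", ")),
                 "ermqsar_validation_error")
  }
  n <- length(id)
  get_num <- function(nm) {
    if (nm %in% names(df)) {
      v <- df[[nm]]
      if (is.character(v)) v[!nzchar(v)] <- NA
      as.numeric(v)
    } else rep(NA_real_, n)
  }
  ec50 <- get_num("ec50_uM")
  pec50 <- get_num("pec50")
  emax <- get_num("emax_pct")
  predicted <- get_num("predicted")
  residual <- get_num("residual")
  if (any(!is.na(ec50) & ec50 <= 0)) {
    stop_ermqsar(sprintf("non-positive EC50 for compound(s): %s",
                         paste(id[!is.na(ec50) & ec50 <= 0], collapse = ", ")),
                 "ermqsar_validation_error")
  }
  split <- if ("split" %in% names(df)) as.character(df$split) else rep("train", n)
  split[is.na(split) | !nzchar(split)] <- "train"
  bad <- !split %in% c("train", "test")
  if (any(bad)) {
    stop_ermqsar(sprintf("unknown split label(s): %s (must be 'train' or 'test')",
                         paste(unique(split[bad]), collapse = ", ")),
                 "ermqsar_validation_error")
  }
  if (any(is.na(ec50) & is.na(pec50))) {
    stop_ermqsar(sprintf("neither EC50 nor pEC50 given for compound(s): %s",
                         paste(id[is.na(ec50) & is.na(pec50)], collapse = ", ")),
                 "ermqsar_validation_error")
  }
  # derive pEC50 from EC50 where absent; flag disagreement where both present
  derive <- is.na(pec50) & !is.na(ec50)
  if (any(derive)) pec50[derive] <- pec50_from_ec50(ec50[derive])
  both <- !is.na(ec50) & !derive
  inconsistent <- rep(FALSE, n)
  if (any(both)) {
    inconsistent[both] <-
      abs(pec50[both] - pec50_from_ec50(ec50[both])) > PEC50_CONSISTENCY_TOL
  }
  out <- data.frame(
    compound_id = id, ec50_uM = ec50, pec50 = pec50, emax_pct = emax,
    split = split, predicted = predicted, residual = residual,
    inconsistent = inconsistent, stringsAsFactors = FALSE
  )
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Read a descriptor matrix from CSV
#'
#' Expects a header `compound_id,<name1>,<name2>,...` and a fully numeric
#' body. Every malformed cell is reported with its row and column; nothing is
#' imputed.
#'
#' @param path path to a CSV file.
#' @return Numeric matrix, rows named by compound id, columns by descriptor
#'   name, in file order.
#' @export
read_descriptor_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L || names(df)[1L] != "compound_id") {
    stop_ermqsar("descriptor CSV must start with a `compound_id` column and have at least one descriptor",
                 "ermqsar_parse_error")
  }
  ids <- df[[1L]]
  dnames <- names(df)[-1L]
  if (anyDuplicated(ids)) {
    stop_ermqsar(sprintf("duplicate compound ids: %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                 "ermqsar_parse_error")
  }
  if (anyDuplicated(dnames)) {
    stop_ermqsar(sprintf("duplicate descriptor names: %s",
                         paste(unique(dnames[duplicated(dnames)]), collapse = ", ")),
                 "ermqsar_parse_error")
  }
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(dnames),
              dimnames = list(ids, dnames))
  for (j in seq_along(dnames)) {
    raw <- df[[j + 1L]]
    blank <- is.na(raw) | !nzchar(trimws(raw))
    if (any(blank)) {
      stop_ermqsar(sprintf("missing value at row %d, column '%s'",
                           which(blank)[1L], dnames[j]),
                   "ermqsar_parse_error")
    }
    v <- suppressWarnings(as.numeric(raw))
    if (any(is.na(v))) {
      stop_ermqsar(sprintf("non-numeric value '%s' at row %d, column '%s'",
                           raw[which(is.na(v))[1L]], which(is.na(v))[1L], dnames[j]),
                   "ermqsar_parse_error")
    }
    m[, j] <- v
  }
  m
}

#' Write a descriptor matrix to CSV
#'
#' Values are serialised with 17 significant digits so a write-then-read
#' round trip reproduces the doubles bit-exactly.
#'
#' @param x numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(x, path) {
  x <- as_descriptor_matrix(x)
  body <- apply(x, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x))
  df <- data.frame(compound_id = rownames(x), body,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("compound_id", colnames(x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an activity table from CSV
#'
#' Columns: `compound_id`, `ec50_uM` and/or `pec50`, optional `emax_pct`,
#' `split`, `predicted`, `residual`; empty cells mean absent. Validation and
#' pEC50 derivation follow [activity_records()].
#'
#' @param path path to a CSV file.
#' @return An `activity_table` data frame.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  activity_records(df)
}

#' Write an activity table to CSV
#'
#' @param x an `activity_table` (or compatible data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(x, path) {
  keep <- intersect(c("compound_id", "ec50_uM", "pec50", "emax_pct",
                      "split", "predicted", "residual"), names(x))
  utils::write.csv(as.data.frame(x)[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# validate a descriptor matrix: numeric, named, unique, no missing values
as_descriptor_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (names(x)[1L] == "compound_id") {
      ids <- as.character(x[[1L]])
      x <- as.matrix(x[-1L])
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_ermqsar("descriptors must be a numeric matrix", "ermqsar_validation_error")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_ermqsar("descriptor matrix needs compound ids as rownames and descriptor names as colnames",
                 "ermqsar_validation_error")
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop_ermqsar("compound ids and descriptor names must be unique",
                 "ermqsar_validation_error")
  }
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop_ermqsar(sprintf("missing/non-finite descriptor value for compound '%s', descriptor '%s'",
                         rownames(x)[bad[1L]], colnames(x)[bad[2L]]),
                 "ermqsar_validation_error")
  }
  x
}

#' Bundle descriptors and activities into a QSAR dataset
#'
#' Strictly aligns a compounds-by-descriptors matrix with a table of activity
#' records: the two compound-id sets must be identical (no silent dropping),
#' and the activity rows are reordered to the descriptor row order.
#'
#' @param descriptors numeric matrix (compounds x descriptors) with unique
#'   row and column names, or a data frame whose first column is
#'   `compound_id`.
#' @param activities data frame acceptable to [activity_records()].
#' @param response_name name of the activity column used as the modelled
#'   response (default `"pec50"`).
#' @return An object of class `qsar_dataset`: a list with elements
#'   `descriptors`, `activities`, `response_name`.
#' @export
qsar_dataset <- function(descriptors, activities, response_name = "pec50") {
  descriptors <- as_descriptor_matrix(descriptors)
  if (!inherits(activities, "activity_table")) activities <- activity_records(activities)
  if (!response_name %in% names(activities)) {
    stop_ermqsar(sprintf("response '%s' not found in activities", response_name),
                 "ermqsar_validation_error")
  }
  only_d <- setdiff(rownames(descriptors), activities$compound_id)
  only_a <- setdiff(activities$compound_id, rownames(descriptors))
  if (length(only_d) || length(only_a)) {
    stop_ermqsar(sprintf(
      "compound ids do not align: %s",
      paste(c(if (length(only_d)) sprintf("only in descriptors: %s", paste(only_d, collapse = ", ")),
              if (length(only_a)) sprintf("only in activities: %s", paste(only_a, collapse = ", "))),
            collapse = "; ")),
      "ermqsar_validation_error")
  }
  activities <- activities[match(rownames(descriptors), activities$compound_id), ,
                           drop = FALSE]
  rownames(activities) <- NULL
  if (!any(activities$split == "train")) {
    stop_ermqsar("training subset is empty", "ermqsar_validation_error")
  }
  y <- activities[[response_name]]
  if (any(!is.finite(y))) {
    stop_ermqsar("response contains missing values", "ermqsar_validation_error")
  }
  structure(list(descriptors = descriptors, activities = activities,
                 response_name = response_name),
            class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  a <- x$activities
  cat(sprintf("QSAR dataset: %d compounds x %d descriptors (%d train / %d test), response '%s'\n",
              nrow(x$descriptors), ncol(x$descriptors),
              sum(a$split == "train"), sum(a$split == "test"), x$response_name))
  invisible(x)
}

# training-row helpers used throughout the search/validation code
train_index <- function(dataset) which(dataset$activities$split == "train")
test_index <- function(dataset) which(dataset$activities$split == "test")
response_vector <- function(dataset) dataset$activities[[dataset$response_name]]
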