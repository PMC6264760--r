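# Descriptor-subset selection by minimisation of the regression SD.
#
# Three routes: exhaustive full search (the global-optimum oracle), the
# Replacement Method (greedy position-wise swaps guided by coefficient
# standard errors), and the Enhanced Replacement Method (RM with a forced
# escape move between two RM passes, returning the best model ever visited).

new_selection_result <- function(method, subset, model, sd_trajectory,
                                 initial_subset, seed, n_models_evaluated,
                                 n_singular) {
  structure(list(method = method, subset = subset, model = model,
                 sd_trajectory = sd_trajectory,
                 initial_subset = initial_subset, seed = seed,
                 n_models_evaluated = n_models_evaluated,
                 n_singular = n_singular),
            class = "qsar_selection")
}

#' @export
print.qsar_selection <- function(x, ...) {
  cat(sprintf("%s selection: d = %d, SD = %.4g (%d models evaluated%s)\n",
              x$method, length(x$subset), x$model$sd, x$n_models_evaluated,
              if (x$n_singular > 0) sprintf(", %d singular skipped", x$n_singular) else ""))
  print(x$model)
  invisible(x)
}

check_search_pre <- function(dataset, d) {
  D <- ncol(dataset$descriptors)
  n <- length(train_index(dataset))
  if (!is_scalar_number(d) || d < 1L || d != round(d)) {
    stop_ermqsar("`d` must be a positive integer", "ermqsar_config_error")
  }
  if (d >= D) stop_ermqsar(sprintf("d = %d must be smaller than the pool size D = %d", d, D),
                           "ermqsar_config_error")
  if (n <= d + 1L) {
    stop_ermqsar(sprintf("training rows (%d) must exceed d + 1 = %d", n, d + 1L),
                 "ermqsar_domain_error")
  }
  invisible(TRUE)
}

#' Exhaustive full search over descriptor subsets
#'
#' Enumerates all `choose(D, d)` subsets of the descriptor pool, fits each by
#' OLS on the training rows, and returns the subset with the smallest
#' residual SD — the global optimum against which the heuristic searches are
#' benchmarked. Singular subsets are skipped and counted. Exact SD ties are
#' broken towards the lexicographically smallest sorted name list.
#'
#' @param dataset a [qsar_dataset()].
#' @param d subset size.
#' @param budget refuse to enumerate more than this many subsets
#'   (default `2e5`).
#' @return A `qsar_selection` with `method = "FS"`.
#' @export
full_search <- function(dataset, d, budget = 2e5) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  check_search_pre(dataset, d)
  D <- ncol(dataset$descriptors)
  total <- choose(D, d)
  if (total > budget) {
    stop_ermqsar(sprintf("full search would enumerate %.0f subsets, over the budget of %.0f",
                         total, budget), "ermqsar_budget_error")
  }
  tr <- train_index(dataset)
  X <- dataset$descriptors[tr, , drop = FALSE]
  y <- response_vector(dataset)[tr]
  nms <- colnames(X)
  best_sd <- Inf
  best_idx <- NULL
  best_key <- NULL
  n_sing <- 0L
  combs <- utils::combn(D, d)
  for (i in seq_len(ncol(combs))) {
    idx <- combs[, i]
    s <- subset_sd(X, y, idx)
    if (is.na(s)) { n_sing <- n_sing + 1L; next }
    if (s < best_sd) {
      best_sd <- s; best_idx <- idx
      best_key <- paste(sort(nms[idx]), collapse = "\r")
    } else if (s == best_sd) {
      key <- paste(sort(nms[idx]), collapse = "\r")
      if (key < best_key) { best_idx <- idx; best_key <- key }
    }
  }
  if (is.null(best_idx)) {
    stop_ermqsar("every candidate subset was singular", "ermqsar_singular_fit")
  }
  subset <- nms[best_idx]
  new_selection_result(
    method = "FS", subset = subset, model = fit_ols(dataset, subset),
    sd_trajectory = data.frame(step = 0L, sd = best_sd),
    initial_subset = NULL, seed = NA_integer_,
    n_models_evaluated = ncol(combs) - n_sing, n_singular = n_sing
  )
}

# One RM engine run from a given subset. A cycle visits each of the d
# positions once, in decreasing order of the relative standard error of the
# current coefficients (recomputed after every accepted swap); at the chosen
# position all D - d outside descriptors are tried and the best
# strictly-SD-decreasing swap is accepted (candidate ties go to the lowest
# column index). Cycles repeat until one completes with no change.
# `tracker` is an environment accumulating the best subset ever evaluated
# and the total model count (shared across ERM phases).
rm_engine <- function(X, y, idx, tracker, use_relative_se = TRUE) {
  D <- ncol(X)
  d <- length(idx)
  n <- nrow(X)
  cur_fit <- ols_core(X[, idx, drop = FALSE], y)
  if (is.null(cur_fit)) {
    stop_ermqsar(sprintf("singular fit at subset {%s}",
                         paste(colnames(X)[idx], collapse = ", ")),
                 "ermqsar_singular_fit")
  }
  cur_sd <- sqrt(cur_fit$rss / (n - d - 1L))
  track_eval(tracker, idx, cur_sd)
  traj_sd <- cur_sd
  repeat {
    changed <- FALSE
    tried <- rep(FALSE, d)
    while (!all(tried)) {
      pos <- pick_position(X, y, idx, tried, use_relative_se)
      out_cols <- setdiff(seq_len(D), idx)
      cand_idx <- idx
      best_cand_sd <- Inf
      best_cand <- NA_integer_
      for (cand in out_cols) {
        cand_idx[pos] <- cand
        s <- subset_sd(X, y, cand_idx)
        track_eval(tracker, cand_idx, s)
        if (!is.na(s) && s < best_cand_sd) { best_cand_sd <- s; best_cand <- cand }
      }
      if (!is.na(best_cand) && best_cand_sd < cur_sd) {
        idx[pos] <- best_cand
        cur_sd <- best_cand_sd
        changed <- TRUE
        traj_sd <- c(traj_sd, cur_sd)
      }
      tried[pos] <- TRUE
    }
    if (!changed) break
  }
  list(idx = idx, sd = cur_sd, traj_sd = traj_sd)
}

# position whose current coefficient is least precisely estimated
pick_position <- function(X, y, idx, tried, use_relative_se) {
  fit <- ols_core(X[, idx, drop = FALSE], y)
  if (is.null(fit)) return(which(!tried)[1L])
  n <- nrow(X)
  d <- length(idx)
  sigma2 <- fit$rss / (n - d - 1L)
  se <- ols_se(fit, sigma2)[-1L]          # drop intercept
  score <- if (use_relative_se) se / abs(fit$coefficients[-1L]) else se
  score[!is.finite(score)] <- Inf          # zero coefficient: maximally uncertain
  score[tried] <- -Inf
  which.max(score)
}

track_eval <- function(tracker, idx, s) {
  tracker$n_eval <- tracker$n_eval + 1L
  if (is.na(s)) {
    tracker$n_singular <- tracker$n_singular + 1L
  } else if (s < tracker$best_sd) {
    tracker$best_sd <- s
    tracker$best_idx <- idx
  }
  invisible(NULL)
}

new_tracker <- function() {
  tracker <- new.env(parent = emptyenv())
  tracker$n_eval <- 0L
  tracker$n_singular <- 0L
  tracker$best_sd <- Inf
  tracker$best_idx <- NULL
  tracker
}

# random initial subset from the current RNG stream; re-drawn if singular
draw_initial <- function(X, y, d, max_tries = 100L) {
  D <- ncol(X)
  attempted <- character(0)
  for (i in seq_len(max_tries)) {
    idx <- sort(sample.int(D, d))
    if (!is.na(subset_sd(X, y, idx))) return(idx)
    attempted <- c(attempted, paste(colnames(X)[idx], collapse = "+"))
  }
  stop_ermqsar(sprintf("could not draw a non-singular initial subset; attempted: %s",
                       paste(attempted, collapse = "; ")),
               "ermqsar_singular_fit")
}

# forced pass: visit every position once in decreasing order of the current
# coefficient's relative SE and swap in the best outside descriptor even when
# the SD does not improve — the escape move that lets the search leave local
# minima of the SD landscape.
forced_pass <- function(X, y, idx, tracker, use_relative_se = TRUE) {
  D <- ncol(X)
  tried <- rep(FALSE, length(idx))
  while (!all(tried)) {
    pos <- pick_position(X, y, idx, tried, use_relative_se)
    cand_idx <- idx
    best_sd <- Inf
    best <- NA_integer_
    for (cand in setdiff(seq_len(D), idx)) {
      cand_idx[pos] <- cand
      s <- subset_sd(X, y, cand_idx)
      track_eval(tracker, cand_idx, s)
      if (!is.na(s) && s < best_sd) { best_sd <- s; best <- cand }
    }
    if (!is.na(best)) idx[pos] <- best
    tried[pos] <- TRUE
  }
  idx
}

#' Replacement Method descriptor-subset selection
#'
#' Starts from a random size-`d` subset (seeded, recorded) and iteratively
#' replaces one descriptor at a time: within each cycle the position whose
#' coefficient carries the largest relative standard error (among positions
#' not yet visited this cycle) is examined, all `D - d` outside descriptors
#' are tried in that position, and the swap giving the largest strict SD
#' decrease is accepted. Cycles repeat until a full pass changes nothing.
#' Deterministic given `(dataset, d, seed)`.
#'
#' @inheritParams full_search
#' @param seed integer seed for the random initial subset.
#' @param use_relative_se rank positions by SE/|coefficient| (default) or by
#'   absolute SE.
#' @return A `qsar_selection` with `method = "RM"`; its `sd_trajectory`
#'   records the SD after the initial fit and each accepted swap and is
#'   non-increasing.
#' @export
replacement_method <- function(dataset, d, seed, use_relative_se = TRUE) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  check_search_pre(dataset, d)
  tr <- train_index(dataset)
  X <- dataset$descriptors[tr, , drop = FALSE]
  y <- response_vector(dataset)[tr]
  idx0 <- with_seed(seed, draw_initial(X, y, d))
  tracker <- new_tracker()
  run <- rm_engine(X, y, idx0, tracker, use_relative_se)
  subset <- colnames(X)[run$idx]
  new_selection_result(
    method = "RM", subset = subset, model = fit_ols(dataset, subset),
    sd_trajectory = data.frame(step = seq_along(run$traj_sd) - 1L, sd = run$traj_sd),
    initial_subset = colnames(X)[idx0], seed = as.integer(seed),
    n_models_evaluated = tracker$n_eval, n_singular = tracker$n_singular
  )
}

#' Enhanced Replacement Method descriptor-subset selection
#'
#' The Replacement Method augmented with forced-replacement escape moves so
#' the search can leave local minima of the SD landscape. The chain is:
#' (1) a full RM run from the seeded random subset; then up to `max_phases`
#' phases, each consisting of (2) a forced pass — every position, taken in
#' decreasing order of its coefficient's relative standard error, is swapped
#' for its best outside alternative even when the SD does not improve —
#' followed by (3) another full RM run. When a phase lands on an RM fixed
#' point already visited, the chain instead perturbs the best subset found
#' so far at a few randomly chosen positions (2, 3 or 4 in rotation, drawn
#' from the seeded stream) before the next RM run. The best-SD subset
#' evaluated anywhere along the chain is returned, so the ERM result is
#' never worse than the RM result from the same seed, and the whole
#' procedure is deterministic given `(dataset, d, seed)`.
#'
#' @inheritParams replacement_method
#' @param max_phases maximum number of escape phases (default 30); the chain
#'   stops early when a perfect fit (SD below 1e-14) is found.
#' @return A `qsar_selection` with `method = "ERM"`; its `sd_trajectory`
#'   records the running best SD after each phase (non-increasing by
#'   construction).
#' @export
enhanced_replacement_method <- function(dataset, d, seed, use_relative_se = TRUE,
                                        max_phases = 30L) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  check_search_pre(dataset, d)
  tr <- train_index(dataset)
  X <- dataset$descriptors[tr, , drop = FALSE]
  y <- response_vector(dataset)[tr]
  D <- ncol(X)
  tracker <- new_tracker()
  kick_sizes <- c(2L, 3L, 4L)

  # the braced block is evaluated lazily in this frame, so its assignments
  # (idx0, traj) are visible after with_seed() returns
  with_seed(seed, {
    idx0 <- draw_initial(X, y, d)
    run <- rm_engine(X, y, idx0, tracker, use_relative_se)
    idx <- run$idx
    seen <- paste(sort(idx), collapse = "+")
    traj <- tracker$best_sd
    n_kicks <- 0L
    for (phase in seq_len(max_phases)) {
      if (tracker$best_sd < 1e-14) break
      idx2 <- forced_pass(X, y, idx, tracker, use_relative_se)
      run <- rm_engine(X, y, idx2, tracker, use_relative_se)
      key <- paste(sort(run$idx), collapse = "+")
      if (key %in% seen) {
        # chain cycled: perturb the best subset so far and descend again
        n_kicks <- n_kicks + 1L
        size <- min(kick_sizes[1L + (n_kicks %% length(kick_sizes))], d, D - d)
        idx2 <- tracker$best_idx
        idx2[sample.int(d, size)] <- sample(setdiff(seq_len(D), idx2), size)
        if (is.na(subset_sd(X, y, idx2))) next
        run <- rm_engine(X, y, idx2, tracker, use_relative_se)
        key <- paste(sort(run$idx), collapse = "+")
      }
      seen <- c(seen, key)
      idx <- run$idx
      traj <- c(traj, tracker$best_sd)
    }
  })

  subset <- colnames(X)[tracker$best_idx]
  new_selection_result(
    method = "ERM", subset = subset, model = fit_ols(dataset, subset),
    sd_trajectory = data.frame(step = seq_along(traj) - 1L, sd = traj),
    initial_subset = colnames(X)[idx0], seed = as.integer(seed),
    n_models_evaluated = tracker$n_eval, n_singular = tracker$n_singular
  )
}

#' Run a subset search by name
#'
#' @inheritParams replacement_method
#' @param method one of `"erm"`, `"rm"`, `"fs"`.
#' @param budget full-search enumeration budget (ignored by RM/ERM).
#' @return A `qsar_selection`.
#' @export
select_descriptors <- function(dataset, d, method = c("erm", "rm", "fs"),
                               seed = 1L, budget = 2e5) {
  method <- match.arg(method)
  switch(method,
         erm = enhanced_replacement_method(dataset, d, seed),
         rm = replacement_method(dataset, d, seed),
         fs = full_search(dataset, d, budget = budget))
}

#' Compare model sizes by cross-validated performance
#'
#' Runs the Enhanced Replacement Method at each size in `d_range`, attaches
#' leave-one-out and (when a test set exists) external validation, and
#' tabulates R2_train, Q2_loo and R2_test per size — the conventional
#' model-size comparison table. The flagged best size maximises Q2_loo, with
#' ties going to the larger R2_test.
#'
#' @inheritParams replacement_method
#' @param d_range integer vector of candidate subset sizes (e.g. `2:5`);
#'   capped by [max_subset_size()] of the training set.
#' @return An object of class `qsar_size_scan`: list with `comparison` (one
#'   row per size: `n`, `r2_train`, `q2_loo`, `r2_test`, `sd_train`,
#'   `sd_cv`), `results` (per-size list of `selection` and `validation`) and
#'   `best_d`.
#' @export
select_model_size <- function(dataset, d_range, seed = 1L) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  d_range <- sort(unique(as.integer(d_range)))
  cap <- max_subset_size(length(train_index(dataset)))
  if (any(d_range < 1L) || any(d_range > cap)) {
    stop_ermqsar(sprintf("d_range must lie within [1, %d] (the 20%% subset-size cap)", cap),
                 "ermqsar_config_error")
  }
  results <- list()
  rows <- vector("list", length(d_range))
  for (i in seq_along(d_range)) {
    d <- d_range[i]
    sel <- enhanced_replacement_method(dataset, d, seed)
    val <- validation_report(dataset, sel$subset)
    results[[as.character(d)]] <- list(selection = sel, validation = val)
    rows[[i]] <- data.frame(
      n = d, r2_train = sel$model$r2, q2_loo = val$q2_loo,
      r2_test = if (is.null(val$r2_test)) NA_real_ else val$r2_test,
      sd_train = sel$model$sd, sd_cv = val$sd_cv
    )
  }
  comparison <- do.call(rbind, rows)
  ord <- order(-comparison$q2_loo,
               -ifelse(is.na(comparison$r2_test), -Inf, comparison$r2_test))
  best_d <- comparison$n[ord[1L]]
  structure(list(comparison = comparison, results = results, best_d = best_d,
                 seed = as.integer(seed)),
            class = "qsar_size_scan")
}

#' @export
print.qsar_size_scan <- function(x, ...) {
  cat("Model-size comparison (ERM selection per size):\n")
  tab <- x$comparison
  tab[-1L] <- lapply(tab[-1L], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("Best size by Q2_loo: d = %d\n", x$best_d))
  invisible(x)
}
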