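# End-to-end pipeline: prune -> select -> fit -> validate -> predict, with
# JSON/CSV artifacts whose bytes are reproducible from (config, seed).

#' Configure a pipeline run
#'
#' Exactly one input source: either `descriptors` + `activities` CSV paths,
#' or a synthetic `simulate` spec (a [synthetic_spec()] or a path to a
#' YAML/JSON file holding its fields).
#'
#' @param descriptors,activities CSV paths (file mode).
#' @param simulate a [synthetic_spec()], or path to a YAML/JSON spec file.
#' @param threshold correlation-prune threshold.
#' @param d subset size, or integer vector to scan (e.g. `2:5`).
#' @param method `"erm"`, `"rm"` or `"fs"`.
#' @param seed root seed recorded in every artifact.
#' @param restarts search restarts.
#' @param out_dir output directory (created if absent).
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(descriptors = NULL, activities = NULL, simulate = NULL,
                       threshold = 0.75, d = NULL, method = "erm", seed = 1L,
                       restarts = 1L, out_dir, log_level = "info") {
  file_mode <- !is.null(descriptors) || !is.null(activities)
  if (file_mode == !is.null(simulate)) {
    stop_ermqsar("exactly one input source: descriptors+activities CSVs XOR a simulate spec",
                 "ermqsar_config_error")
  }
  if (file_mode) {
    if (is.null(descriptors) || is.null(activities)) {
      stop_ermqsar("file mode needs both `descriptors` and `activities` paths",
                   "ermqsar_config_error")
    }
    for (p in c(descriptors, activities)) {
      if (!file.exists(p)) {
        stop_ermqsar(sprintf("input file does not exist: %s", p), "ermqsar_config_error")
      }
    }
  }
  structure(list(descriptors = descriptors, activities = activities,
                 simulate = simulate, threshold = threshold, d = d,
                 method = method, seed = as.integer(seed),
                 restarts = as.integer(restarts), out_dir = out_dir,
                 log_level = log_level),
            class = "run_config")
}

read_spec_file <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_ermqsar("reading YAML specs needs the 'yaml' package", "ermqsar_config_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(fields$correlated_blocks) && is.matrix(fields$correlated_blocks)) {
    fields$correlated_blocks <- split(fields$correlated_blocks,
                                      seq_len(nrow(fields$correlated_blocks)))
  }
  do.call(synthetic_spec, fields)
}

# stable hash of the configuration, for the run manifest
config_hash <- function(config) {
  plain <- lapply(unclass(config), function(x) if (inherits(x, "synthetic_spec")) unclass(x) else x)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  path
}

#' Run the full modelling pipeline
#'
#' Loads (or simulates) the data, prunes the descriptor pool, selects a
#' descriptor subset, fits and validates the model, and writes the artifact
#' set to `config$out_dir`:
#' `pruned_descriptors.csv`, `prune_report.json`, `selection.json`,
#' `model.json`, `equation.txt`, `validation.json`, `predictions.csv`
#' (compound, observed, predicted, residual, split), `comparison.csv` (when
#' `d` is a range) and `manifest.json` (seed, config hash, package version,
#' md5 of every artifact). All artifacts are byte-reproducible from
#' (config, seed); a failing stage raises an error prefixed with its stage
#' name.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the fitted `qsar_mlr` and the artifact
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(stage, msg) {
    if (!identical(config$log_level, "quiet")) message(sprintf("[%s] %s", stage, msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  dataset <- stage("load", {
    if (!is.null(config$simulate)) {
      spec <- config$simulate
      if (is.character(spec)) spec <- read_spec_file(spec)
      say("load", sprintf("simulating pool (seed %d)", spec$seed))
      generate_pool(spec)$dataset
    } else {
      say("load", sprintf("reading %s / %s", config$descriptors, config$activities))
      qsar_dataset(read_descriptor_csv(config$descriptors),
                   read_activity_csv(config$activities))
    }
  })

  fit <- stage("model", {
    say("model", sprintf("prune (|r| > %g) + %s selection, seed %d",
                         config$threshold, toupper(config$method), config$seed))
    qsar_mlr(dataset, d = config$d, method = config$method, seed = config$seed,
             restarts = config$restarts, threshold = config$threshold)
  })

  artifacts <- character(0)
  add <- function(p) { artifacts <<- c(artifacts, p); p }
  stage("report", {
    write_descriptor_csv(fit$dataset$descriptors, add(out("pruned_descriptors.csv")))
    write_json_artifact(prune_report_as_list(fit$prune_report),
                        add(out("prune_report.json")))
    sel <- fit$selection
    write_json_artifact(list(
      method = sel$method, subset = sel$subset,
      initial_subset = sel$initial_subset, seed = sel$seed,
      n_models_evaluated = sel$n_models_evaluated, n_singular = sel$n_singular,
      sd_trajectory = sel$sd_trajectory, final_sd = sel$model$sd
    ), add(out("selection.json")))
    write_json_artifact(model_as_list(fit$model), add(out("model.json")))
    writeLines(render_equation(fit$model), add(out("equation.txt")))
    val <- fit$validation
    write_json_artifact(list(
      n = length(fit$model$subset), r2_train = fit$model$r2,
      q2_loo = val$q2_loo, sd_cv = val$sd_cv,
      r2_test = if (is.null(val$r2_test)) NULL else val$r2_test
    ), add(out("validation.json")))
    preds <- val$predictions
    preds[c("observed", "predicted", "residual")] <-
      lapply(preds[c("observed", "predicted", "residual")],
             function(v) sprintf("%.17g", v))
    utils::write.csv(preds, add(out("predictions.csv")), row.names = FALSE,
                     quote = FALSE)
    if (!is.null(fit$size_scan)) {
      cmp <- fit$size_scan$comparison
      cmp[-1L] <- lapply(cmp[-1L], function(v) sprintf("%.17g", v))
      utils::write.csv(cmp, add(out("comparison.csv")), row.names = FALSE,
                       quote = FALSE)
    }
    manifest <- list(
      package = "ermqsar",
      version = as.character(utils::packageVersion("ermqsar")),
      seed = config$seed,
      config_hash = config_hash(config),
      checksums = as.list(stats::setNames(unname(tools::md5sum(artifacts)),
                                          basename(artifacts)))
    )
    write_json_artifact(manifest, out("manifest.json"))
  })
  say("done", sprintf("%d artifacts in %s", length(artifacts) + 1L, config$out_dir))
  invisible(list(fit = fit, artifacts = c(artifacts, out("manifest.json"))))
}

#' Recomputed prediction report for the embedded benchmark
#'
#' Takes the embedded 35-compound fixture, recomputes each residual as
#' printed-observed minus published-predicted pEC50, and compares it with
#' the printed residual at 3 decimal places (the table's precision,
#' round-half-even). The one arithmetically inconsistent printed residual
#' (compound 23) shows up as `residual_matches = FALSE`; rows whose printed
#' pEC50 disagrees with their EC50 keep their `inconsistent` flag.
#'
#' @return Data frame: compound, observed and predicted pEC50, recomputed
#'   and printed residual, split, `inconsistent`, `residual_matches`.
#' @export
table4_report <- function() {
  f <- table4_fixture()
  recomputed <- activity_residual(f$pec50, f$predicted)
  data.frame(
    compound_id = f$compound_id,
    observed = f$pec50, predicted = f$predicted,
    residual = recomputed, printed_residual = f$residual,
    split = f$split, inconsistent = f$inconsistent,
    residual_matches = round(recomputed, 3) == round(f$residual, 3),
    stringsAsFactors = FALSE
  )
}
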