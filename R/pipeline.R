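# File I/O, run configuration and the end-to-end pipeline.

.mandatory_cols <- c("subject_id", "age")
.known_cols <- c("subject_id", "cohort", "sex", "race", "age", "bmi",
                 "bmi_pct", "sbp", "dbp", "bp_pct", "total_chol", "glucose",
                 "bp_med", "lipid_med", "glucose_med", "cvh_score")
.numeric_cols <- c("age", "bmi", "bmi_pct", "sbp", "dbp", "bp_pct",
                   "total_chol", "glucose", "cvh_score")
.flag_cols <- c("bp_med", "lipid_med", "glucose_med")

#' Read a long-format examination CSV
#'
#' Reads per-examination records with the documented schema (one row per
#' subject-visit). `subject_id` and `age` are mandatory; unknown columns are
#' ignored with a warning; rows with unparseable or out-of-range values in
#' mandatory fields are dropped with a warning, unless more than half the
#' rows fail, which is a fatal format error.
#'
#' @param path CSV path.
#' @return data frame of validated examination records. The number of
#'   rejected rows is attached as attribute `n_rejected`.
#' @export
read_cvh_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = TRUE)
  miss <- setdiff(.mandatory_cols, names(raw))
  if (length(miss))
    stop("format error: missing mandatory columns: ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(raw), .known_cols)
  if (length(extra))
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
  raw <- raw[, intersect(.known_cols, names(raw)), drop = FALSE]
  if (!nrow(raw)) {
    warning("empty input file (header only)")
    for (cl in intersect(.numeric_cols, names(raw)))
      raw[[cl]] <- numeric(0)
    return(raw)
  }
  out <- raw
  for (cl in intersect(.numeric_cols, names(out))) {
    v <- suppressWarnings(as.numeric(out[[cl]]))
    v[!is.na(out[[cl]]) & nzchar(trimws(out[[cl]])) & is.na(v)] <- NaN
    out[[cl]] <- v
  }
  for (cl in intersect(.flag_cols, names(out)))
    out[[cl]] <- tolower(trimws(out[[cl]])) %in% c("true", "t", "1", "yes")
  bad <- !nzchar(trimws(out$subject_id)) |
    is.nan(out$age) | is.na(out$age) | out$age < 0 | out$age >= 120
  pct_bad <- c("bmi_pct", "bp_pct")
  for (cl in intersect(pct_bad, names(out)))
    bad <- bad | (!is.na(out[[cl]]) & (is.nan(out[[cl]]) |
                                         out[[cl]] < 0 | out[[cl]] > 100))
  for (cl in intersect(.numeric_cols, names(out)))
    out[[cl]][is.nan(out[[cl]])] <- NA_real_
  if (mean(bad) > 0.5)
    stop(sprintf("format error: %d of %d rows failed validation",
                 sum(bad), length(bad)))
  if (any(bad))
    warning(sprintf("dropped %d of %d rows failing validation",
                    sum(bad), length(bad)))
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write a long-format examination CSV
#'
#' @param data examination records.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cvh_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Exactly one of `input` (CSV path) or `preset` (generator preset name)
#' must be given.
#'
#' @param input path to a long-format examination CSV.
#' @param preset name of a generator preset (see [cvh_preset()]).
#' @param out_dir output run directory (created if needed).
#' @param covariates adjustment covariates for the segmented fit.
#' @param n_changepoints number of change points to estimate (0-2).
#' @param stratify optional column name: refit the segmented model within
#'   each level (e.g. `"sex"`).
#' @param knots optional fixed knots for the interaction model; default is
#'   the rounded estimated change points.
#' @param group grouping factor of the interaction model.
#' @param seed RNG seed for simulation.
#' @param n_subjects optional subject count override for presets.
#' @return object of class `cvh_run_config`.
#' @export
run_config <- function(input = NULL, preset = NULL, out_dir,
                       covariates = c("race", "sex", "cohort"),
                       n_changepoints = 2, stratify = NULL, knots = NULL,
                       group = "sex", seed = 1L, n_subjects = NULL) {
  if (is.null(input) == is.null(preset))
    stop("specify exactly one of 'input' or 'preset'")
  structure(list(input = input, preset = preset, out_dir = out_dir,
                 covariates = covariates, n_changepoints = n_changepoints,
                 stratify = stratify, knots = knots, group = group,
                 seed = as.integer(seed), n_subjects = n_subjects),
            class = "cvh_run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [run_config()].
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# internal: deterministic polynomial rolling hash of a deparsed object
# (config stamp for the manifest; not cryptographic)
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# internal: drop lme4 model objects so results are JSON-serializable
.json_segmented <- function(fit) {
  list(n_changepoints = fit$n_changepoints,
       psi = fit$psi, beta = as.list(fit$beta), delta = fit$delta,
       gamma = fit$gamma, segment_slopes = fit$segment_slopes,
       vc = fit$vc, loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
       converged = fit$converged, trace = fit$trace)
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate-or-load, score + completeness filter, segmented fit
#' (overall, then stratified if requested), model comparison, fixed-knot
#' interaction model, descriptive tables. All randomness flows from the
#' config seed, so a rerun with the same config writes byte-identical JSON
#' results. Outputs (scored CSV, JSON fit results, comparison and
#' descriptive tables, a manifest, and a plain-text log) land in
#' `config$out_dir`; a stage failure aborts with the stage name after
#' persisting completed outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the run directory, the manifest, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cvh_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  logmsg <- function(...) {
    line <- paste0(...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  stages_done <- character()
  results <- list()
  run_stage <- function(name, fn) {
    logmsg("stage: ", name)
    res <- tryCatch(fn(), error = function(e) {
      logmsg("stage FAILED: ", name, ": ", conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stages_done <<- c(stages_done, name)
    res
  }
  wjson <- function(x, file)
    jsonlite::write_json(x, file.path(config$out_dir, file),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "columns")

  results$data <- run_stage("input", function() {
    if (!is.null(config$preset)) {
      cfg <- cvh_preset(config$preset, seed = config$seed,
                        n_subjects = config$n_subjects)
      if (cfg$raw_metric_mode) generate_raw_metrics(cfg)
      else generate_cvh_scores(cfg)
    } else {
      read_cvh_csv(config$input)
    }
  })

  results$scored <- run_stage("score", function() {
    sc <- score_dataset(results$data)
    write_cvh_csv(sc$data, file.path(config$out_dir, "scored.csv"))
    wjson(sc$report, "inclusion.json")
    sc
  })
  d <- results$scored$data
  covs <- intersect(config$covariates, names(d))
  covs <- covs[vapply(covs, function(cl) length(unique(d[[cl]])) > 1, TRUE)]

  results$segmented <- run_stage("segmented_fit", function() {
    fit <- fit_segmented(d, n_changepoints = config$n_changepoints,
                         covariates = covs)
    out <- list(overall = .json_segmented(fit))
    if (!is.null(config$stratify) && config$stratify %in% names(d)) {
      strata <- setdiff(covs, config$stratify)
      for (lev in sort(unique(as.character(d[[config$stratify]])))) {
        sub <- d[d[[config$stratify]] == lev, , drop = FALSE]
        scovs <- strata[vapply(strata, function(cl)
          length(unique(sub[[cl]])) > 1, TRUE)]
        out[[paste0(config$stratify, "_", lev)]] <- .json_segmented(
          fit_segmented(sub, n_changepoints = config$n_changepoints,
                        covariates = scovs))
      }
    }
    wjson(out, "segmented.json")
    attr(out, "fit") <- fit
    out
  })

  results$comparison <- run_stage("model_comparison", function() {
    cmp <- compare_models(d, covariates = covs)
    wjson(list(table = cmp$table, lrt = cmp$lrt, best_aic = cmp$best_aic,
               best_bic = cmp$best_bic), "comparison.json")
    write.csv(cmp$table, file.path(config$out_dir, "comparison.csv"),
              row.names = FALSE)
    cmp
  })

  results$piecewise <- run_stage("piecewise_interaction", function() {
    fit <- attr(results$segmented, "fit")
    knots <- config$knots
    if (is.null(knots)) {
      knots <- if (fit$n_changepoints > 0) round(fit$psi$estimate)
      else c(17, 37)
    }
    pw <- fit_piecewise_interaction(
      d, knots = knots, group = config$group,
      adjust = setdiff(covs, config$group))
    wjson(list(knots = pw$knots, segment_bounds = pw$segment_bounds,
               group_slopes = pw$group_slopes,
               differences = pw$differences, means_at_8 = pw$means_at_8,
               loglik = pw$loglik, aic = pw$aic, bic = pw$bic),
          "piecewise.json")
    write.csv(pw$group_slopes,
              file.path(config$out_dir, "piecewise_slopes.csv"),
              row.names = FALSE)
    pw
  })

  results$baseline <- run_stage("descriptives", function() {
    bt <- baseline_table(d)
    write.csv(bt$numeric, file.path(config$out_dir, "baseline_numeric.csv"),
              row.names = FALSE)
    if (!is.null(bt$categorical))
      write.csv(bt$categorical,
                file.path(config$out_dir, "baseline_categorical.csv"),
                row.names = FALSE)
    bt
  })

  manifest <- list(
    package = "cvhseg",
    version = as.character(utils::packageVersion("cvhseg")),
    config = unclass(config),
    config_hash = .config_hash(unclass(config)),
    seed = config$seed,
    stages = stages_done
  )
  wjson(manifest, "manifest.json")
  logmsg("pipeline complete: ", length(stages_done), " stages")
  invisible(list(out_dir = config$out_dir, manifest = manifest,
                 results = results))
}
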