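# End-to-end orchestration: simulate -> preprocess -> windows -> features ->
# train -> evaluate, with a validated hierarchical configuration, per-stage
# artifacts and a manifest. Every stochastic component derives from the
# single global seed.

#' Default pipeline configuration
#'
#' Nested sections mirror the stage constructors: `data` ([sim_params()]
#' plus `n_per_class`), `preprocess` ([preprocess_config()]), `augment`
#' ([augment_config()]), `welch` ([welch_config()]), `model`
#' ([model_config()] preset and overrides) and `train` ([train_config()]).
#' Unknown keys anywhere fail validation before any stage runs.
#'
#' @param seed Global seed propagated to simulation, splitting and training.
#' @param out_dir Run directory for artifacts and logs.
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, out_dir = "ppgfusion-run") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    data = list(n_per_class = 10L, fs = 250, duration_s = 300),
    preprocess = list(),
    augment = list(),
    welch = list(),
    model = list(preset = "small"),
    train = list(epochs = 15L, verbose = FALSE),
    split = list(ratios = c(0.6, 0.2, 0.2))
  ), class = "run_config")
}

section_formals <- function() list(
  data = c("n_per_class", names(formals(sim_params))),
  preprocess = names(formals(preprocess_config)),
  augment = names(formals(augment_config)),
  welch = names(formals(welch_config)),
  model = c("preset", "fs", "window_s", "n_classes", "dropout",
            "use_residual", "use_csia", "use_cross_attention", "branches",
            names(fdma_presets$paper)),
  train = names(formals(train_config)),
  split = "ratios"
)

#' Validate a pipeline configuration
#'
#' Checks the section structure and every key against the stage
#' constructors; all violations are reported together.
#'
#' @param config Nested list (see [default_run_config()]).
#' @return The validated config (invisibly classed `run_config`).
#' @export
validate_run_config <- function(config) {
  base <- default_run_config()
  bad <- character()
  unknown_sections <- setdiff(names(config), names(base))
  bad <- c(bad, sprintf("unknown section '%s'", unknown_sections))
  allowed <- section_formals()
  for (sec in intersect(names(config), names(allowed))) {
    extra <- setdiff(names(config[[sec]]), allowed[[sec]])
    bad <- c(bad, sprintf("unknown key '%s.%s'", sec, extra))
  }
  pp <- utils::modifyList(base$preprocess %||% list(), config$preprocess %||% list())
  if (!is.null(pp$band_low_hz) && !is.null(pp$band_high_hz) &&
      pp$band_low_hz >= pp$band_high_hz)
    bad <- c(bad, "preprocess.band_low_hz must be below preprocess.band_high_hz")
  if (length(bad))
    abort(paste("invalid configuration:\n ", paste(bad, collapse = "\n  ")),
          "config_error")
  merged <- utils::modifyList(unclass(base), config, keep.null = TRUE)
  invisible(structure(merged, class = "run_config"))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the [default_run_config()] structure.
#' @return Validated `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

stage_path <- function(dir, name) file.path(dir, paste0(name, ".rds"))

load_or_run <- function(dir, name, resume, fn) {
  p <- stage_path(dir, name)
  if (resume && file.exists(p)) return(readRDS(p))
  val <- fn()
  saveRDS(val, p)
  val
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, split + WASW windowing, spectral feature
#' extraction, training and evaluation, writing per-stage artifacts, a
#' manifest, the training history and the evaluation report under
#' `config$out_dir`. A rerun with `resume = TRUE` restarts from the first
#' missing artifact.
#'
#' @param config A `run_config` (list or YAML path accepted).
#' @param resume Reuse existing stage artifacts.
#' @param until Last stage to execute: one of `"dataset"`, `"preprocessed"`,
#'   `"windows"`, `"features"`, `"model"`, `"evaluate"` (default: all).
#' @return Invisibly, a list with the artifacts produced so far (fitted
#'   model and evaluation report when those stages ran) and the run
#'   directory.
#' @export
run_pipeline <- function(config = default_run_config(), resume = FALSE,
                         until = "evaluate") {
  stages <- c("dataset", "preprocessed", "windows", "features", "model",
              "evaluate")
  until <- match.arg(until, stages)
  done <- function(stage) match(stage, stages) >= match(until, stages)
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  data_args <- config$data
  sp <- do.call(sim_params, c(data_args[setdiff(names(data_args), "n_per_class")],
                              list(seed = config$seed)))
  records <- load_or_run(config$out_dir, "dataset", resume, function() {
    ds <- make_dataset(data_args$n_per_class, sp)
    utils::write.csv(dataset_manifest(ds),
                     file.path(config$out_dir, "manifest.csv"),
                     row.names = FALSE)
    ds
  })
  if (done("dataset"))
    return(invisible(list(records = records, dir = config$out_dir)))

  pcfg <- do.call(preprocess_config, config$preprocess)
  clean <- load_or_run(config$out_dir, "preprocessed", resume,
                       function() preprocess_dataset(records, pcfg))
  if (done("preprocessed"))
    return(invisible(list(records = clean, dir = config$out_dir)))

  acfg <- do.call(augment_config, config$augment)
  wins <- load_or_run(config$out_dir, "windows", resume, function() {
    split <- stratified_split(clean, config$split$ratios, seed = config$seed)
    utils::write.csv(split, file.path(config$out_dir, "split.csv"),
                     row.names = FALSE)
    build_window_sets(clean, split, acfg)
  })
  if (done("windows"))
    return(invisible(list(windows = wins, dir = config$out_dir)))

  wcfg <- do.call(welch_config, config$welch)
  margs <- config$model
  mcfg <- do.call(model_config,
                  c(margs[setdiff(names(margs), "preset")],
                    list(preset = margs$preset %||% "small", fs = sp$fs,
                         welch = wcfg)))
  feats <- load_or_run(config$out_dir, "features", resume, function() {
    lapply(wins, function(ws)
      window_ssm_tensor(ws$windows, sp$fs, wcfg, mcfg$n_bands))
  })
  if (done("features"))
    return(invisible(list(windows = wins, features = feats,
                          dir = config$out_dir)))

  tcfg <- do.call(train_config,
                  utils::modifyList(config$train, list(seed = config$seed)))
  model <- load_or_run(config$out_dir, "model", resume, function() {
    m <- fusion_dma(wins$train$windows, wins$train$labels,
                    ssm = feats$train, config = mcfg, train = tcfg,
                    x_val = wins$val$windows, y_val = wins$val$labels,
                    ssm_val = feats$val,
                    source_ids = wins$train$source_ids,
                    val_source_ids = wins$val$source_ids,
                    class_weights = attr(wins, "class_weights"))
    utils::write.csv(m$history, file.path(config$out_dir, "history.csv"),
                     row.names = FALSE)
    m
  })
  if (done("model"))
    return(invisible(list(model = model, dir = config$out_dir)))

  report <- evaluate_model(model, wins$test$windows, wins$test$labels,
                           ssm = feats$test)
  utils::write.csv(as.data.frame(report$confusion),
                   file.path(config$out_dir, "confusion.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_class,
                   file.path(config$out_dir, "per_class_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(per_class = report$per_class, overall = report$overall,
         roc = report$roc),
    file.path(config$out_dir, "eval_report.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(list(model = model, report = report, dir = config$out_dir))
}
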