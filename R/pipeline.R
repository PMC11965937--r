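## Declarative end-to-end runs: one YAML config with a section per stage,
## a master seed propagated to every stochastic step, and a manifest of
## produced artifacts with content hashes.

default_pipeline_config <- function() {
  list(
    master_seed = 20260101L,
    out_dir = "emgfatigue_run",
    stages = list(simulate = TRUE, preprocess = TRUE, decompose = TRUE,
                  features = TRUE, embed = TRUE, classify = TRUE),
    synth = list(n_subjects = 2, n_trials = 2, n_channels = 1, duration = 20,
                 fs = 1000, mdf_start = 90, mdf_end = 60, rms_gain_end = 1.8,
                 bandwidth = 60, powerline_amp = 0.1, drift_amp = 0.5,
                 sensor_noise_sd = 0.05, label_fraction = 1 / 3),
    preprocess = list(band_low = 20, band_high = 450, filter_order = 4,
                      notch_freq = 50, notch_q = 30, zero_phase = TRUE),
    decompose = list(variant = "ICEEMDAN", max_imfs = 8, ensemble_size = 20,
                     noise_strength = 0.2),
    features = list(window_len = 1000, overlap = 0.5, k_keep = 4),
    tsne = list(perplexity = 30, n_iter = 500, learning_rate = 200),
    classify = list(kind = "svm", scheme = "stratified-window", k_folds = 5)
  )
}

read_config_file <- function(config_path) {
  if (!file.exists(config_path))
    stop("config file not found: ", config_path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(config_path), error = function(e)
    stop("config parse error: ", conditionMessage(e), call. = FALSE))
  if (is.null(cfg)) cfg <- list()
  cfg
}

merge_section <- function(user, default, section, notes) {
  out <- default
  for (key in names(user)) {
    if (!key %in% names(default)) {
      warning(sprintf("unknown config key `%s` in section `%s`", key, section),
              call. = FALSE)
      next
    }
    out[[key]] <- user[[key]]
    notes$rows[[length(notes$rows) + 1L]] <-
      data.frame(section = section, key = key,
                 value = paste(format(user[[key]]), collapse = ","),
                 source = "user")
  }
  for (key in setdiff(names(default), names(user))) {
    notes$rows[[length(notes$rows) + 1L]] <-
      data.frame(section = section, key = key,
                 value = paste(format(default[[key]]), collapse = ","),
                 source = "default")
  }
  out
}

#' Validate a pipeline config file and echo resolved parameters
#'
#' Reads the YAML config, overlays it on the package defaults, warns on
#' unknown keys and reports every resolved parameter with its source
#' (`user` / `default`). No side effects.
#'
#' @param config_path path to a YAML config file.
#' @return A list with `config` (the resolved configuration) and `report`
#'   (data frame: section, key, value, source).
#' @export
validate_config <- function(config_path) {
  user <- read_config_file(config_path)
  defaults <- default_pipeline_config()
  notes <- new.env()
  notes$rows <- list()
  resolved <- list()
  scalar_keys <- c("master_seed", "out_dir")
  for (key in scalar_keys) {
    if (!is.null(user[[key]])) {
      resolved[[key]] <- user[[key]]
      notes$rows[[length(notes$rows) + 1L]] <-
        data.frame(section = "top", key = key,
                   value = format(user[[key]]), source = "user")
    } else {
      resolved[[key]] <- defaults[[key]]
      notes$rows[[length(notes$rows) + 1L]] <-
        data.frame(section = "top", key = key,
                   value = format(defaults[[key]]), source = "default")
    }
  }
  for (section in c("stages", "synth", "preprocess", "decompose", "features",
                    "tsne", "classify")) {
    resolved[[section]] <- merge_section(user[[section]] %||% list(),
                                         defaults[[section]], section, notes)
  }
  known <- c(scalar_keys, "stages", "synth", "preprocess", "decompose",
             "features", "tsne", "classify")
  for (key in setdiff(names(user), known))
    warning(sprintf("unknown config key `%s`", key), call. = FALSE)
  report <- do.call(rbind, notes$rows)
  ## an explicitly emptied section required by an enabled stage is a schema error
  if (isTRUE(resolved$stages$embed) &&
      "tsne" %in% names(user) && is.null(user$tsne))
    stop("config schema error: section `tsne` is empty but the embed stage is enabled",
         call. = FALSE)
  list(config = resolved, report = report)
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  writeLines(msg, con)
}

#' Run the full fatigue-detection pipeline from a config file
#'
#' Executes simulate -> preprocess -> decompose -> features -> embed ->
#' classify (each stage can be toggled off), writing every intermediate
#' artifact (record CSVs, IMF CSVs, feature table, embedding, evaluation
#' JSON), a timestamped run log, and `manifest.csv` listing each artifact
#' with its MD5 content hash.
#'
#' @param config_path path to a YAML config file (see [validate_config()]).
#' @return Invisibly, a list with the output directory, the manifest data
#'   frame and the evaluation report (if the classify stage ran).
#' @export
run_pipeline <- function(config_path) {
  cfg <- validate_config(config_path)$config
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logc <- file(log_path, open = "wt")
  on.exit(close(logc))
  artifacts <- character(0)
  log_line(logc, "master_seed = ", cfg$master_seed)

  stage_failed <- function(stage, e) {
    log_line(logc, "STAGE FAILED: ", stage, " -- ", conditionMessage(e))
    write_manifest(out_dir, artifacts)
    stop("pipeline aborted in stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  }

  records <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    log_line(logc, "stage simulate")
    tryCatch({
      sc <- do.call(synth_config, c(cfg$synth, list(master_seed = cfg$master_seed)))
      records <- generate_dataset(sc)
      rec_dir <- file.path(out_dir, "records")
      write_records(records, rec_dir)
      artifacts <- c(artifacts, file.path("records",
                                          list.files(rec_dir)))
    }, error = function(e) stage_failed("simulate", e))
  }

  if (isTRUE(cfg$stages$preprocess) && !is.null(records)) {
    log_line(logc, "stage preprocess")
    tryCatch({
      pc <- do.call(preprocess_config, cfg$preprocess)
      records <- lapply(records, preprocess_record, config = pc)
      pre_dir <- file.path(out_dir, "preprocessed")
      write_records(records, pre_dir)
      artifacts <- c(artifacts, file.path("preprocessed",
                                          list.files(pre_dir)))
    }, error = function(e) stage_failed("preprocess", e))
  }

  decomps <- NULL
  if (isTRUE(cfg$stages$decompose) && !is.null(records)) {
    log_line(logc, "stage decompose (", cfg$decompose$variant, ")")
    tryCatch({
      dp <- decomp_params(max_imfs = cfg$decompose$max_imfs,
                          ensemble_size = cfg$decompose$ensemble_size,
                          noise_strength = cfg$decompose$noise_strength,
                          seed = cfg$master_seed,
                          variant = cfg$decompose$variant)
      imf_dir <- file.path(out_dir, "imfs")
      dir.create(imf_dir, showWarnings = FALSE)
      decomps <- lapply(names(records), function(nm) {
        d <- decompose(records[[nm]]$samples, dp)
        write_imfs(d, file.path(imf_dir, paste0(nm, "_imfs.csv")),
                   fs = records[[nm]]$fs)
        d
      })
      names(decomps) <- names(records)
      artifacts <- c(artifacts, file.path("imfs", list.files(imf_dir)))
    }, error = function(e) stage_failed("decompose", e))
  }

  table <- NULL
  if (isTRUE(cfg$stages$features) && !is.null(records)) {
    log_line(logc, "stage features")
    tryCatch({
      wc <- window_config(window_len = cfg$features$window_len,
                          overlap = cfg$features$overlap)
      table <- extract_feature_table(records, decomps, wc,
                                     k_keep = if (is.null(decomps)) 0
                                              else cfg$features$k_keep)
      write_feature_table(table, file.path(out_dir, "features.csv"))
      artifacts <- c(artifacts, "features.csv")
    }, error = function(e) stage_failed("features", e))
  }

  emb <- NULL
  wide <- NULL
  if (!is.null(table)) {
    wide <- feature_table_wide(table, if (is.null(decomps)) 0 else cfg$features$k_keep)
  }
  if (isTRUE(cfg$stages$embed) && !is.null(wide)) {
    log_line(logc, "stage embed")
    tryCatch({
      emb <- embed_feature_table(wide,
                                 perplexity = cfg$tsne$perplexity,
                                 n_iter = cfg$tsne$n_iter,
                                 learning_rate = cfg$tsne$learning_rate,
                                 seed = cfg$master_seed)
      utils::write.csv(emb, file.path(out_dir, "embedding.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(iter = seq_along(attr(emb, "embedding")$cost_trace),
                   kl = attr(emb, "embedding")$cost_trace),
        file.path(out_dir, "tsne_cost_trace.csv"), row.names = FALSE)
      artifacts <- c(artifacts, "embedding.csv", "tsne_cost_trace.csv")
    }, error = function(e) stage_failed("embed", e))
  }

  report <- NULL
  if (isTRUE(cfg$stages$classify) && !is.null(wide)) {
    log_line(logc, "stage classify")
    tryCatch({
      report <- cross_validate(wide, scheme = cfg$classify$scheme,
                               k_folds = cfg$classify$k_folds,
                               kind = cfg$classify$kind,
                               seed = cfg$master_seed)
      jsonlite::write_json(
        list(kind = report$kind, scheme = report$scheme,
             mean_accuracy = report$mean_accuracy,
             pooled_accuracy = report$pooled_accuracy,
             folds = report$folds, seed = report$seed),
        file.path(out_dir, "eval_report.json"), auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, "eval_report.json")
    }, error = function(e) stage_failed("classify", e))
  }

  log_line(logc, "writing manifest")
  manifest <- write_manifest(out_dir, artifacts)
  invisible(list(out_dir = out_dir, manifest = manifest, report = report))
}

write_manifest <- function(out_dir, artifacts) {
  paths <- file.path(out_dir, artifacts)
  ok <- file.exists(paths)
  manifest <- data.frame(artifact = artifacts[ok],
                         md5 = unname(tools::md5sum(paths[ok])),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
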