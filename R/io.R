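# Dataset serialization and the end-to-end pipeline.
#
# All artifacts are plain text: CSV for tables and series (floats printed
# with 17 significant digits so doubles round-trip exactly), JSON for
# parameters and manifests. Every artifact-producing step writes exactly
# one manifest.json carrying the command, seed, configuration snapshot,
# package version, timestamp and an md5 content hash per file.

fmt_num <- function(x) sprintf("%.17g", x)

write_table_17 <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
}

write_manifest <- function(dir, command, seed, config, files, extra = list()) {
  paths <- file.path(dir, files)
  manifest <- c(list(
    command = command,
    package = "aclgait",
    version = as.character(packageVersion("aclgait")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    files = lapply(stats::setNames(paths, files), function(p)
      list(md5 = unname(tools::md5sum(p)), bytes = file.size(p)))),
    extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_manifest <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) abort("missing manifest.json in '%s'", dir)
  jsonlite::read_json(mp, simplifyVector = TRUE)
}

check_integrity <- function(dir, manifest) {
  for (f in names(manifest$files)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) abort("missing dataset file '%s'", f)
    h <- unname(tools::md5sum(p))
    if (!identical(h, manifest$files[[f]]$md5))
      abort("integrity failure: '%s' hash %s does not match manifest %s",
            f, h, manifest$files[[f]]$md5)
  }
}

#' Write / read a preprocessed cohort bundle
#'
#' `write_dataset()` serializes a `gait_cohort` into a directory:
#' `profiles.csv` (one row per subject), `records.csv` (record table with
#' labels), `series.csv` (time-normalized channels in long form),
#' `oracle_params.json` and a `manifest.json` with md5 content hashes.
#' `read_dataset()` restores the bundle, rejecting missing files and any
#' file whose hash no longer matches the manifest. Floats round-trip
#' exactly (17 significant digits); identifiers and enums round-trip
#' verbatim.
#'
#' @param cohort A `gait_cohort`.
#' @param dir Target (creatable) / source directory.
#' @return `write_dataset()`: the written paths, invisibly.
#'   `read_dataset()`: the restored `gait_cohort`.
#' @export
write_dataset <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_17(cohort$profiles, file.path(dir, "profiles.csv"))
  rec <- cohort$meta
  rec$acl_force_bw <- cohort$labels
  write_table_17(rec, file.path(dir, "records.csv"))
  d <- dim(cohort$series)
  ser <- data.frame(
    record_id = rep(seq_len(d[3]), each = d[1] * d[2]),
    channel = rep(cohort$channels, times = d[2] * d[3]),
    point = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    value = fmt_num(as.numeric(cohort$series)))
  write.csv(ser, file.path(dir, "series.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$oracle, file.path(dir, "oracle_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c("profiles.csv", "records.csv", "series.csv",
             "oracle_params.json")
  write_manifest(dir, "write_dataset", cohort$seed,
                 c(cohort$preprocess,
                   list(cycles_per_subject = cohort$cycles_per_subject,
                        group_split = cohort$group_split,
                        channels = cohort$channels)),
                 files)
  invisible(file.path(dir, c(files, "manifest.json")))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- read_manifest(dir)
  check_integrity(dir, manifest)
  profiles <- read.csv(file.path(dir, "profiles.csv"),
                       stringsAsFactors = FALSE)
  class(profiles) <- c("subject_profile", "data.frame")
  rec <- read.csv(file.path(dir, "records.csv"), stringsAsFactors = FALSE)
  ser <- read.csv(file.path(dir, "series.csv"), stringsAsFactors = FALSE)
  channels <- unlist(manifest$config$channels)
  n_points <- manifest$config$n_points
  n_rec <- nrow(rec)
  series <- array(ser$value, dim = c(length(channels), n_points, n_rec))
  dimnames(series) <- list(channels, NULL, NULL)
  structure(list(profiles = profiles, series = series,
                 labels = rec$acl_force_bw,
                 meta = rec[, c("record_id", "subject_id", "cycle_index",
                                "group")],
                 n_points = as.integer(n_points), channels = channels,
                 preprocess = manifest$config[c("order", "cutoff",
                                                "grf_threshold",
                                                "min_separation",
                                                "n_points")],
                 oracle = jsonlite::read_json(
                   file.path(dir, "oracle_params.json"),
                   simplifyVector = TRUE),
                 seed = manifest$seed,
                 cycles_per_subject = manifest$config$cycles_per_subject,
                 group_split = manifest$config$group_split),
            class = "gait_cohort")
}

#' Write a raw simulated cohort bundle
#'
#' Serializes a [simulate_cohort_raw()] result: `profiles.csv`,
#' `labels.csv`, `streams.csv` (per-subject concatenated raw series in
#' long form, native sampling rates) plus `oracle_params.json` and a
#' hashed manifest.
#'
#' @param raw A `gait_raw` object.
#' @param dir Target directory.
#' @return Written paths, invisibly.
#' @export
write_raw_dataset <- function(raw, dir) {
  stopifnot(inherits(raw, "gait_raw"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_17(raw$profiles, file.path(dir, "profiles.csv"))
  write_table_17(raw$labels, file.path(dir, "labels.csv"))
  per <- lapply(seq_along(raw$streams), function(i) {
    st <- raw$streams[[i]]
    data.frame(
      subject_id = i,
      channel = c(rep(rownames(st$kin), each = ncol(st$kin)),
                  rep("grf", length(st$grf))),
      sample = c(rep(seq_len(ncol(st$kin)), times = nrow(st$kin)),
                 seq_along(st$grf)),
      value = fmt_num(c(t(st$kin)[TRUE], st$grf)))
  })
  write.csv(do.call(rbind, per), file.path(dir, "streams.csv"),
            row.names = FALSE)
  jsonlite::write_json(raw$oracle, file.path(dir, "oracle_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c("profiles.csv", "labels.csv", "streams.csv",
             "oracle_params.json")
  write_manifest(dir, "simulate", raw$seed,
                 list(n_subjects = raw$n_subjects,
                      cycles_per_subject = raw$cycles_per_subject,
                      group_split = raw$group_split,
                      fs_kin = raw$params$gait$fs_kin,
                      fs_grf = raw$params$gait$fs_grf),
                 files)
  invisible(file.path(dir, c(files, "manifest.json")))
}

# Serialize / restore model parameters as JSON (text checkpoint).
write_params_json <- function(params, path) {
  enc <- lapply(params, function(p)
    list(dim = dim(p) %||% length(p), data = as.numeric(p)))
  jsonlite::write_json(enc, path, auto_unbox = FALSE, digits = NA)
}

read_params_json <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(enc, function(e) {
    d <- as.integer(e$dim)
    if (length(d) == 1L) as.numeric(e$data)
    else array(as.numeric(e$data), dim = d)
  })
}

pipeline_schema <- list(
  top = c("seed", "out_dir", "simulate", "preprocess", "model", "train",
          "evaluate", "compare"),
  simulate = c("n_subjects", "cycles_per_subject", "group_split"),
  preprocess = c("order", "cutoff", "grf_threshold", "min_separation",
                 "n_points", "include_rom_t3"),
  model = c("channels", "kernel_size", "dilations", "dropout",
            "static_units", "head_units", "head_dropout", "readout",
            "lstm_units"),
  train = c("epochs", "batch_size", "learning_rate", "grid", "grid_epochs"),
  evaluate = c("grouping"),
  compare = c("enabled", "models", "epochs"))

validate_config <- function(config) {
  check <- function(keys, allowed, where) {
    bad <- setdiff(keys, allowed)
    if (length(bad))
      abort("unknown %s configuration key(s): %s", where,
            paste(bad, collapse = ", "))
  }
  check(names(config), pipeline_schema$top, "top-level")
  for (sec in setdiff(pipeline_schema$top, c("seed", "out_dir")))
    if (!is.null(config[[sec]]))
      check(names(config[[sec]]), pipeline_schema[[sec]], sec)
  invisible(config)
}

config_spec <- function(config, kind = "hybrid") {
  m <- config$model %||% list()
  model_spec(kind = kind,
             tcn = tcn_config(channels = m$channels %||% 32,
                              kernel_size = m$kernel_size %||% 3,
                              dilations = unlist(m$dilations) %||% c(1, 2, 4),
                              dropout = m$dropout %||% 0.2),
             static_units = unlist(m$static_units) %||% 16,
             head_units = unlist(m$head_units) %||% c(32, 16),
             head_dropout = m$head_dropout %||% 0.2,
             readout = m$readout %||% "last",
             lstm_units = m$lstm_units %||% 32)
}

#' Run the full simulate / preprocess / train / evaluate / compare chain
#'
#' Executes the end-to-end pipeline from one configuration document (YAML
#' or JSON file, or an equivalent named list) under a single master seed,
#' writing one artifact directory per stage, each with a hashed manifest.
#' Unknown configuration keys are rejected. Re-running the same
#' configuration reproduces `evaluate/folds.csv` exactly.
#'
#' @param config Path to a YAML/JSON configuration, or a named list.
#' @param out_dir Output directory (overrides `out_dir` in the config).
#' @param seed Master seed (overrides `seed` in the config).
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the cohort, fitted model,
#'   cross-validation summary, comparison table (if enabled) and artifact
#'   paths.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         quiet = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  validate_config(config)
  seed <- seed %||% config$seed %||% 1
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) abort("out_dir must be given (argument or config)")
  say <- function(...) if (!quiet) message(sprintf(...))
  sim <- config$simulate %||% list()
  pre <- config$preprocess %||% list()
  trn <- config$train %||% list()
  evl <- config$evaluate %||% list()
  cmp <- config$compare %||% list()

  say("[simulate] %s subjects x %s cycles",
      sim$n_subjects %||% 44, sim$cycles_per_subject %||% 10)
  raw <- simulate_cohort_raw(
    n_subjects = sim$n_subjects %||% 44,
    cycles_per_subject = sim$cycles_per_subject %||% 10,
    group_split = sim$group_split %||% 0.5,
    seed = derive_seed(seed, 101))
  write_raw_dataset(raw, file.path(out_dir, "simulate"))

  say("[preprocess] cutoff %s Hz, threshold %s N, %s points",
      pre$cutoff %||% 20, pre$grf_threshold %||% 10, pre$n_points %||% 101)
  cohort <- preprocess_cohort(raw,
    order = pre$order %||% 4, cutoff = pre$cutoff %||% 20,
    grf_threshold = pre$grf_threshold %||% 10,
    min_separation = pre$min_separation %||% 0.4,
    n_points = pre$n_points %||% 101)
  write_dataset(cohort, file.path(out_dir, "preprocess"))
  include_rom_t3 <- isTRUE(pre$include_rom_t3)

  spec <- config_spec(config, "hybrid")
  tc <- train_config(epochs = trn$epochs %||% 1000,
                     batch_size = trn$batch_size %||% 32,
                     adam = adam_hyper(alpha = trn$learning_rate %||% 0.001))
  train_dir <- file.path(out_dir, "train")
  dir.create(train_dir, recursive = TRUE, showWarnings = FALSE)
  scaler <- fit_static_scaler(cohort$profiles, include_rom_t3)
  statics <- cohort_statics(cohort, scaler)
  grid_files <- character(0)
  if (isTRUE(trn$grid)) {
    say("[train] grid search")
    gs <- grid_search(default_grid(), cohort$series, statics,
                      cohort$labels, spec, tc,
                      epochs = trn$grid_epochs %||% 100,
                      seed = derive_seed(seed, 201))
    spec <- gs$best$spec
    tc <- gs$best$config
    tc$epochs <- as.integer(trn$epochs %||% 1000)
    write_table_17(gs$table, file.path(train_dir, "grid_scores.csv"))
    grid_files <- "grid_scores.csv"
  }
  say("[train] %d epochs, batch %d", tc$epochs, tc$batch_size)
  fit <- train_model(cohort$series, statics, cohort$labels, spec, tc,
                     seed = derive_seed(seed, 202))
  write_params_json(fit$params, file.path(train_dir, "checkpoint.json"))
  spec_plain <- unclass(fit$spec)
  spec_plain$tcn <- unclass(spec_plain$tcn)
  jsonlite::write_json(spec_plain, file.path(train_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_table_17(data.frame(epoch = seq_along(fit$loss_history),
                            mse = fit$loss_history),
                 file.path(train_dir, "loss_history.csv"))
  write_manifest(train_dir, "train", seed,
                 list(epochs = tc$epochs, batch_size = tc$batch_size,
                      learning_rate = tc$adam$alpha,
                      grid = isTRUE(trn$grid)),
                 c("checkpoint.json", "spec.json", "loss_history.csv",
                   grid_files))

  say("[evaluate] three-fold cross-validation (%s grouping)",
      evl$grouping %||% "cycle")
  cv <- run_cv(cohort, spec, tc, seed = derive_seed(seed, 301),
               grouping = evl$grouping %||% "cycle",
               include_rom_t3 = include_rom_t3)
  ev_dir <- file.path(out_dir, "evaluate")
  dir.create(ev_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_17(cv$folds, file.path(ev_dir, "folds.csv"))
  jsonlite::write_json(list(mean_test_r2 = cv$mean_test_r2,
                            mean_test_rmse = cv$mean_test_rmse,
                            incomplete = cv$incomplete),
                       file.path(ev_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  scatter_files <- character(0)
  for (f in names(cv$predictions)) {
    if (is.null(cv$predictions[[f]])) next
    fn <- sprintf("scatter_fold_%s.csv", f)
    write_table_17(cv$predictions[[f]], file.path(ev_dir, fn))
    scatter_files <- c(scatter_files, fn)
  }
  write_manifest(ev_dir, "evaluate", seed,
                 list(grouping = evl$grouping %||% "cycle"),
                 c("folds.csv", "summary.json", scatter_files))

  comparison <- NULL
  if (isTRUE(cmp$enabled)) {
    models <- unlist(cmp$models) %||% c("hybrid", "tcn_only", "lstm")
    say("[compare] %s", paste(models, collapse = ", "))
    specs <- stats::setNames(lapply(models, function(k)
      config_spec(config, k)), models)
    ctc <- tc
    if (!is.null(cmp$epochs)) ctc$epochs <- as.integer(cmp$epochs)
    comparison <- compare_models(cohort, specs, ctc,
                                 seed = derive_seed(seed, 401),
                                 include_rom_t3 = include_rom_t3)
    cp_dir <- file.path(out_dir, "compare")
    dir.create(cp_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_17(comparison$table, file.path(cp_dir, "comparison.csv"))
    write_manifest(cp_dir, "compare", seed, list(models = models),
                   "comparison.csv")
  }
  say("[done] artifacts under %s", out_dir)
  invisible(list(cohort = cohort, fit = fit, cv = cv,
                 comparison = comparison, out_dir = out_dir, seed = seed))
}
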