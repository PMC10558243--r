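# End-to-end orchestration: simulate -> preprocess -> featurize ->
# train/evaluate (-> sweep), with on-disk artifacts and stage resumption.

#' Configuration of a full pipeline run
#'
#' @param synth A [synth_config()] for the simulated session.
#' @param filter A [filter_spec()].
#' @param window A [window_spec()].
#' @param undersample_factor Decimation factor after filtering.
#' @param models Character vector of model kinds to evaluate
#'   (subset of `"rf"`, `"svm"`, `"knn"`, `"mlp"`), or a list of
#'   [model_grid()]s.
#' @param test_fraction Held-out test proportion per class interval.
#' @param n_outer,n_inner Nested-CV fold counts.
#' @param sweep Run the window-length sweep stage?
#' @param sweep_grid RF grid for the sweep stage.
#' @param seed Master seed for the whole run.
#' @return A `run_config` list.
#' @export
run_config <- function(synth = synth_config(), filter = filter_spec(),
                       window = window_spec(), undersample_factor = 2L,
                       models = "rf", test_fraction = 0.1,
                       n_outer = 10L, n_inner = 3L,
                       sweep = FALSE,
                       sweep_grid = model_grid("rf", num_trees = 200,
                                               max_depth = 20),
                       seed = 1L) {
  if (is.character(models)) {
    models <- lapply(models, model_grid)
  }
  stopifnot(inherits(synth, "synth_config"), inherits(filter, "filter_spec"),
            inherits(window, "window_spec"),
            all(vapply(models, inherits, logical(1), "model_grid")))
  structure(
    list(synth = synth, filter = filter, window = window,
         undersample_factor = as.integer(undersample_factor),
         models = models, test_fraction = test_fraction,
         n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
         sweep = isTRUE(sweep), sweep_grid = sweep_grid,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Write a session to a directory
#'
#' The signal block is stored as a flat little-endian double array
#' (`signal.bin`, channel-major) with a JSON metadata sidecar (`meta.json`:
#' dimensions, sampling rate, intervals, channel status, generator config);
#' physiological traces and ground-truth spike times are exported as CSV.
#'
#' @param session An `eng_session`.
#' @param dir Output directory (created if missing).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "eng_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "signal.bin"), "wb")
  writeBin(as.vector(session$signal), con, size = 8L, endian = "little")
  close(con)
  meta <- list(
    n_channels = nrow(session$signal), n_samples = ncol(session$signal),
    fs = session$fs,
    intervals = session$intervals,
    channel_status = as.character(session$channel_status),
    config = strip_classes(session$config),
    preprocess = strip_classes(session$preprocess)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(session$physio)) {
    utils::write.csv(
      data.frame(time_s = (seq_along(session$physio$pressure) - 1) /
                   session$physio$fs,
                 pressure = session$physio$pressure,
                 volume = session$physio$volume),
      file.path(dir, "physio.csv"), row.names = FALSE)
  }
  if (!is.null(session$ground_truth) && nrow(session$ground_truth)) {
    utils::write.csv(session$ground_truth,
                     file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory.
#' @return An `eng_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(file.path(dir, "signal.bin"), "rb")
  signal <- matrix(readBin(con, "double", n = n, size = 8L,
                           endian = "little"),
                   nrow = meta$n_channels)
  close(con)
  intervals <- as.data.frame(meta$intervals)
  intervals$state <- factor(intervals$state, levels = STATE_LEVELS)
  physio <- NULL
  pfile <- file.path(dir, "physio.csv")
  if (file.exists(pfile)) {
    pv <- utils::read.csv(pfile)
    fsp <- if (!is.null(meta$config$fs_physio)) meta$config$fs_physio else
      1 / mean(diff(pv$time_s))
    physio <- list(pressure = pv$pressure, volume = pv$volume, fs = fsp)
  }
  gt <- NULL
  gfile <- file.path(dir, "ground_truth.csv")
  if (file.exists(gfile)) gt <- utils::read.csv(gfile)
  cfg <- meta$config
  if (!is.null(cfg)) {
    cfg$state_rates <- unlist(cfg$state_rates)
    cfg$state_amplitudes <- unlist(cfg$state_amplitudes)
    class(cfg) <- "synth_config"
  }
  structure(
    list(signal = signal, fs = meta$fs, intervals = intervals,
         channel_status = factor(meta$channel_status,
                                 levels = c("functional", "dead")),
         physio = physio, ground_truth = gt, config = cfg,
         preprocess = meta$preprocess),
    class = "eng_session"
  )
}

#' Run the full decoding pipeline
#'
#' Executes simulate -> preprocess -> featurize -> train/evaluate (and
#' optionally the window-length sweep), writing every stage's artifacts
#' under `out_dir`: the raw and preprocessed session directories, train and
#' test feature CSVs plus the scaler JSON, a `report.json` with per-model
#' nested-CV results and held-out evaluation, per-model confusion-matrix
#' CSVs, a frozen `config.json` snapshot, and a `log.txt` with per-stage
#' timings. Numeric results are fully reproducible from the config snapshot;
#' timings live only in the log so reports are byte-stable.
#'
#' If a stage's artifacts already exist under `out_dir` the stage is skipped
#' and its outputs are re-read, so deleting an intermediate directory and
#' re-running resumes from the missing stage.
#'
#' Model evaluation runs [nested_cv()] on the training table (fold-internal
#' standardization and shuffling), then refits each model's modal selected
#' hyperparameters on the standardized full training table and scores it
#' once on the held-out test table.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory for all artifacts.
#' @return Invisibly, a list with the session, feature tables, per-model
#'   `eng_cv` reports, held-out results, and the sweep (if run).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "log.txt")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%OS1"),
                paste0(...)), file = log_file, append = TRUE)
  }
  stage <- function(name, artifact, produce, load) {
    if (length(artifact) > 0L && all(file.exists(artifact))) {
      log_line("stage ", name, ": artifacts present, resuming from disk")
      return(load())
    }
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(produce(), error = function(e) {
      log_line("stage ", name, " FAILED: ", conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_line("stage ", name, sprintf(": done in %.1f s",
                                     proc.time()[["elapsed"]] - t0))
    out
  }

  jsonlite::write_json(serialize_config(config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  raw_dir <- file.path(out_dir, "session")
  session <- stage("simulate", file.path(raw_dir, "meta.json"),
                   function() {
                     s <- generate_session(config$synth)
                     write_session(s, raw_dir)
                     s
                   },
                   function() read_session(raw_dir))

  filt_dir <- file.path(out_dir, "session_filt")
  filtered <- stage("preprocess", file.path(filt_dir, "meta.json"),
                    function() {
                      s <- preprocess_session(session, config$filter,
                                              config$undersample_factor)
                      write_session(s, filt_dir)
                      s
                    },
                    function() read_session(filt_dir))

  feat_train <- file.path(out_dir, "features_train.csv")
  feat_test <- file.path(out_dir, "features_test.csv")
  tables <- stage("featurize", c(feat_train, feat_test),
                  function() {
                    tb <- featurize_session(filtered, config$window,
                                            config$test_fraction)
                    write_features_csv(tb$train, feat_train)
                    write_features_csv(tb$test, feat_test)
                    tb
                  },
                  function() {
                    featurize_session(filtered, config$window,
                                      config$test_fraction)
                  })

  report_file <- file.path(out_dir, "report.json")
  reports <- list()
  holdout <- list()
  for (grid in config$models) {
    kind <- grid$model_kind
    cv <- stage(paste0("train-eval-", kind), character(0), function() {
      nested_cv(tables$train, grid, n_outer = config$n_outer,
                n_inner = config$n_inner, seed = config$seed)
    }, function() NULL)
    reports[[kind]] <- cv
    # held-out evaluation with the modal fold-selected hyperparameters
    params <- modal_params(cv$fold_params)
    std <- standardize(tables$train, tables$test)
    str_ <- shuffle_rows(std$train, derive_seed(config$seed, 77L))
    model <- fit_model(kind, params, str_$x, str_$labels,
                       seed = derive_seed(config$seed, 78L),
                       importance = kind == "rf")
    pred <- predict_model(model, std$test$x)
    cm <- confusion_matrix(std$test$labels, pred)
    holdout[[kind]] <- list(params = params, cm = cm,
                            ba = balanced_accuracy(cm))
    utils::write.csv(as.data.frame(cm),
                     file.path(out_dir, paste0("confusion_", kind, ".csv")))
  }

  sweep_res <- NULL
  if (config$sweep) {
    sweep_res <- stage("sweep", character(0), function() {
      window_sweep(filtered, config$sweep_grid, n_folds = config$n_outer,
                   seed = config$seed)
    }, function() NULL)
    utils::write.csv(sweep_as_data_frame(sweep_res),
                     file.path(out_dir, "sweep.csv"), row.names = FALSE)
  }

  jsonlite::write_json(
    report_payload(reports, holdout, sweep_res, config),
    report_file, auto_unbox = TRUE, digits = 12, pretty = TRUE
  )
  log_line("pipeline complete")
  invisible(list(session = session, filtered = filtered, tables = tables,
                 reports = reports, holdout = holdout, sweep = sweep_res,
                 out_dir = out_dir))
}

# Most frequently selected hyperparameter combination across folds
# (ties broken by first occurrence).
modal_params <- function(fold_params) {
  keys <- vapply(fold_params, function(p) paste(deparse(p), collapse = ""),
                 character(1))
  fold_params[[which.max(tabulate(match(keys, unique(keys))))]]
}

# Recursively drop S3 classes so jsonlite serializes plain lists.
strip_classes <- function(x) {
  if (is.null(x)) return(NULL)
  x <- unclass(x)
  if (is.list(x)) lapply(x, strip_classes) else x
}

serialize_config <- function(config) strip_classes(config)

report_payload <- function(reports, holdout, sweep_res, config) {
  payload <- list(seed = config$seed, models = list())
  for (kind in names(reports)) {
    cv <- reports[[kind]]
    payload$models[[kind]] <- list(
      fold_ba = cv$fold_ba, mean_ba = cv$mean_ba, median_ba = cv$median_ba,
      iqr_ba = cv$iqr_ba,
      selected_params = cv$fold_params,
      pooled_confusion = as.data.frame(as.table(cv$pooled_cm)),
      holdout_ba = holdout[[kind]]$ba,
      holdout_confusion = as.data.frame(as.table(holdout[[kind]]$cm)),
      importance_per_feature = if (!is.null(cv$importance))
        as.list(cv$importance$per_feature) else NULL,
      importance_per_channel = if (!is.null(cv$importance))
        as.list(cv$importance$per_channel) else NULL
    )
  }
  if (!is.null(sweep_res)) {
    payload$sweep <- list(lengths_s = sweep_res$lengths_s,
                          mean_ba = sweep_res$mean_ba,
                          selected_length_s = select_tradeoff(sweep_res))
  }
  payload
}
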