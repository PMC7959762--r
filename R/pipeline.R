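#' Pipeline configuration
#'
#' All tunable parameters of the IHR sleep-staging pipeline in one
#' validated list, with the reference defaults: 4 Hz IHR sampling, 30-s
#' epochs, 90-s (3-epoch) windows, Takens embedding (p, tau) = (120, 1),
#' at least 5 beats per scored epoch, median-filter acceptance band
#' (0.7, 1.4), Rips homology up to dimension 1 at unbounded scale,
#' linear SVM with cost 1 on unstandardized features, subsampling seed
#' 1.  The configuration is embedded in every artifact the pipeline
#' writes.
#'
#' @param fs IHR sampling rate (Hz).
#' @param epoch_s epoch length (s).
#' @param window_epochs epochs per analysis window.
#' @param takens_p,takens_tau embedding dimension and lag.
#' @param min_beats_per_epoch discard rule threshold.
#' @param low_ratio,high_ratio median-filter acceptance band.
#' @param vr_max_dim,vr_max_scale Rips settings.
#' @param svm_cost,svm_standardize classifier settings.
#' @param seed subsampling seed.
#' @param task classification task (`"ws"`, `"rn"`, `"wrn"`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fs = 4, epoch_s = 30, window_epochs = 3L,
                            takens_p = 120L, takens_tau = 1L,
                            min_beats_per_epoch = 5L,
                            low_ratio = 0.7, high_ratio = 1.4,
                            vr_max_dim = 1L, vr_max_scale = Inf,
                            svm_cost = 1, svm_standardize = FALSE,
                            seed = 1L, task = "ws") {
  cfg <- list(
    fs = fs, epoch_s = epoch_s, window_epochs = as.integer(window_epochs),
    takens_p = as.integer(takens_p), takens_tau = as.integer(takens_tau),
    min_beats_per_epoch = as.integer(min_beats_per_epoch),
    low_ratio = low_ratio, high_ratio = high_ratio,
    vr_max_dim = as.integer(vr_max_dim), vr_max_scale = vr_max_scale,
    svm_cost = svm_cost, svm_standardize = svm_standardize,
    seed = as.integer(seed), task = match.arg(task, c("ws", "rn", "wrn"))
  )
  window_len <- cfg$window_epochs * cfg$epoch_s * cfg$fs
  need <- (cfg$takens_p - 1L) * cfg$takens_tau + 1L
  if (window_len < need) {
    abort(sprintf(
      "window of %d samples (%d epochs x %g s x %g Hz) cannot carry a (p = %d, tau = %d) embedding needing %d samples",
      window_len, cfg$window_epochs, cfg$epoch_s, cfg$fs,
      cfg$takens_p, cfg$takens_tau, need
    ))
  }
  structure(cfg, class = "pipeline_config")
}

#' Features of one recording
#'
#' Runs preprocessing and feature extraction for a single subject:
#' median-filter the R peaks, interpolate the IHR at the configured
#' rate, cut labeled median-centered windows, and compute the 48
#' persistence statistics per window.
#'
#' @param recording list with `rpeaks` (tibble `time_s`), `labels`
#'   (tibble `epoch`, `label`) and optionally `subject_id`.
#' @param config a [pipeline_config()].
#' @return Feature tibble (one row per retained epoch).
#' @export
recording_features <- function(recording, config = pipeline_config()) {
  cleaned <- clean_rpeaks(recording$rpeaks, low_ratio = config$low_ratio,
                          high_ratio = config$high_ratio)
  ihr <- compute_ihr(cleaned, fs = config$fs)
  win <- extract_windows(ihr, recording$labels, cleaned,
                         epoch_s = config$epoch_s,
                         window_epochs = config$window_epochs,
                         min_beats = config$min_beats_per_epoch)
  if (nrow(win) == 0) {
    return(dplyr::bind_cols(
      tibble(subject_id = character(0), epoch = integer(0),
             label = character(0)),
      as_tibble(matrix(numeric(0), 0, 48,
                       dimnames = list(NULL, feature_names())))
    ))
  }
  win$subject_id <- recording$subject_id %||% NA_character_
  compute_features(win, p = config$takens_p, tau = config$takens_tau,
                   max_scale = config$vr_max_scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full sleep-staging pipeline
#'
#' End to end: extract features for the training and test recordings,
#' restrict both to the task's epochs, balance the training classes by
#' down-sampling (test epochs are never balanced), train the linear
#' SVM, predict every test epoch, and assemble the evaluation report.
#'
#' @param train_recordings,test_recordings lists of recordings (each a
#'   list with `rpeaks`, `labels`, `subject_id`), or feature tibbles as
#'   returned by [recording_features()] (detected by the presence of a
#'   `label` column in a data frame).
#' @param config a [pipeline_config()].
#' @return A list: `report` (see [per_subject_report()]), `model`,
#'   `train_features`, `test_features`, `predictions`, `config`, and
#'   `log` (epoch counts retained/dropped per stage).
#' @export
run_pipeline <- function(train_recordings, test_recordings,
                         config = pipeline_config()) {
  as_features <- function(x) {
    if (is.data.frame(x)) return(x)
    dplyr::bind_rows(purrr::map(x, recording_features, config = config))
  }
  train_all <- as_features(train_recordings)
  test_all <- as_features(test_recordings)
  train <- task_labels(train_all, config$task)
  test <- task_labels(test_all, config$task)
  if (nrow(train) == 0 || nrow(test) == 0) {
    abort("no epochs left after preprocessing and task filtering")
  }
  balanced <- balance_downsample(train, seed = config$seed)
  model <- train_sleep_svm(balanced, task = config$task,
                           cost = config$svm_cost,
                           standardize = config$svm_standardize)
  predictions <- predict(model, test)
  classes <- classification_tasks()[[config$task]]$classes
  report <- per_subject_report(predictions, classes)
  list(
    report = report, model = model,
    train_features = train_all, test_features = test_all,
    predictions = predictions, config = config,
    log = list(
      train_epochs_featurized = nrow(train_all),
      train_epochs_in_task = nrow(train),
      train_epochs_after_balance = nrow(balanced),
      test_epochs_featurized = nrow(test_all),
      test_epochs_evaluated = nrow(test)
    )
  )
}

#' Write an evaluation report as JSON
#'
#' Serializes the per-subject summary, pooled metrics, confusion counts
#' and the full pipeline configuration (for provenance) to a JSON file.
#'
#' @param result a [run_pipeline()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  rep <- result$report
  cfg <- unclass(result$config)
  if (is.infinite(cfg$vr_max_scale)) cfg$vr_max_scale <- "Inf" # JSON-safe
  payload <- list(
    config = cfg,
    log = result$log,
    summary = rep$summary,
    per_subject = rep$per_subject,
    pooled = list(by_class = rep$pooled$by_class,
                  overall = rep$pooled$overall),
    confusion = list(classes = rownames(rep$confusion),
                     counts = unname(as.matrix(rep$confusion)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
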