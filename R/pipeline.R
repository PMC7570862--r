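# End-to-end orchestration: simulate -> segment -> rebalance -> standardize
# -> split -> pretrain -> fine-tune -> evaluate.

#' Assemble a run configuration
#'
#' Collects every knob of the pipeline. The default `mode = "paper"` stage
#' order is segment, rebalance the *whole* instance set, standardize with
#' statistics fitted on the whole set, then split 6:2:2 — the classical
#' preprocess-then-split ordering. `mode = "leakfree"` splits first, fits
#' the standardizer on the training portion only and rebalances only the
#' training portion, so no information crosses the split.
#'
#' @param protocol A [study_protocol()].
#' @param models Activity models (default [default_activity_models()]).
#' @param window_size,overlap Segmentation parameters (default 512 samples,
#'   50% overlap).
#' @param channels `"acc+gyr"`, `"acc"` or `"gyr"` (sensor ablation).
#' @param plan A [resample_plan()] (default random oversampling).
#' @param split_ratios Train/validation/test ratios (default 6:2:2).
#' @param stratified Stratify the split by class.
#' @param train A [train_config()].
#' @param mode `"paper"` or `"leakfree"` stage ordering.
#' @param average `"micro"` or `"weighted"` summary row to highlight.
#' @param seed Master seed for split and resampling (the training seed lives
#'   in `train$seed`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(protocol = study_protocol(),
                       models = default_activity_models(),
                       window_size = 512, overlap = 0.5,
                       channels = c("acc+gyr", "acc", "gyr"),
                       plan = resample_plan("oversample"),
                       split_ratios = c(0.6, 0.2, 0.2),
                       stratified = FALSE,
                       train = train_config(),
                       mode = c("paper", "leakfree"),
                       average = c("micro", "weighted"),
                       seed = 42) {
  structure(
    list(
      protocol = protocol, models = models,
      window_size = window_size, overlap = overlap,
      channels = match.arg(channels),
      plan = plan, split_ratios = split_ratios, stratified = stratified,
      train = train, mode = match.arg(mode), average = match.arg(average),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Run the full recognition pipeline
#'
#' Executes every stage on a synthetic study (or supplied recordings) in the
#' configured order and returns all artifacts: the fine-tuned model, the
#' evaluation report on the test split, loss/accuracy traces, and a manifest
#' recording seeds and per-stage instance counts so every number is
#' recomputable from the configuration alone.
#'
#' @param config A [run_config()].
#' @param recordings Optional list of [sensor_recording()] objects to use
#'   instead of simulating from `config$protocol`.
#' @param out_dir Optional directory; when given, the model file, metrics
#'   CSVs, traces and a JSON manifest are written there.
#' @param quiet Suppress stage progress messages.
#' @return Object of class `har_run` with elements `model`, `report`,
#'   `split`, `standardizer`, `manifest`.
#' @export
har_run <- function(config, recordings = NULL, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "), ...)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sdaehar")),
    r_version = as.character(getRversion()),
    mode = config$mode, channels = config$channels,
    seeds = list(master = config$seed, protocol = config$protocol$seed,
                 resample = config$plan$seed, train = config$train$seed),
    stages = list()
  )

  if (is.null(recordings)) {
    say("simulate: ", config$protocol$n_subjects, " subjects")
    recordings <- generate_study(config$protocol, config$models)
  }
  manifest$stages$simulate <- list(n_recordings = length(recordings))

  say("segment: window ", config$window_size, ", overlap ", config$overlap)
  instances <- segment_recordings(recordings, config$window_size, config$overlap)
  instances <- select_channels(instances, config$channels)
  manifest$stages$segment <- list(
    n_instances = length(instances),
    instance_length = ncol(instances$X),
    class_counts = as.list(class_counts(instances, drop_empty = TRUE))
  )

  plan <- config$plan
  if (is.null(plan$seed)) plan$seed <- child_seed(config$seed, 11)
  split_seed <- child_seed(config$seed, 12)

  if (config$mode == "paper") {
    say("rebalance (whole set): ", plan$method)
    balanced <- rebalance(instances, plan)
    manifest$stages$rebalance <- list(
      method = plan$method,
      class_counts = as.list(class_counts(balanced, drop_empty = TRUE))
    )
    say("standardize (fit on all)")
    standardizer <- fit_standardizer(balanced)
    scaled <- apply_standardizer(standardizer, balanced)
    say("split ", paste(config$split_ratios, collapse = ":"))
    parts <- split_instances(scaled, config$split_ratios, split_seed, config$stratified)
  } else {
    say("split ", paste(config$split_ratios, collapse = ":"))
    parts <- split_instances(instances, config$split_ratios, split_seed, config$stratified)
    say("rebalance (train only): ", plan$method)
    parts$train <- rebalance(parts$train, plan)
    manifest$stages$rebalance <- list(
      method = plan$method,
      class_counts = as.list(class_counts(parts$train, drop_empty = TRUE))
    )
    say("standardize (fit on train)")
    standardizer <- fit_standardizer(parts$train)
    parts$train <- apply_standardizer(standardizer, parts$train)
    parts$validation <- apply_standardizer(standardizer, parts$validation)
    parts$test <- apply_standardizer(standardizer, parts$test)
  }
  manifest$stages$split <- list(
    train = length(parts$train), validation = length(parts$validation),
    test = length(parts$test)
  )

  say("pretrain: stack ", paste(config$train$hidden_sizes, collapse = "-"),
      ", ", config$train$pretrain_epochs, " epochs/layer")
  model <- pretrain_stack(parts$train, config$train)

  say("fine-tune: ", config$train$finetune_epochs, " epochs")
  model <- fine_tune(model, parts$train, parts$validation, config$train)

  say("evaluate on ", length(parts$test), " test instances")
  pred <- predict(model, parts$test, type = "class")
  report <- metrics_report(parts$test$label, pred, class_order = model$classes)
  manifest$stages$evaluate <- list(
    test_accuracy = overall_metrics(report$confusion, "micro")$accuracy
  )

  result <- structure(
    list(model = model, report = report, split = parts,
         standardizer = standardizer, manifest = manifest),
    class = "har_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_sdae(model, file.path(out_dir, "model.sdae"))
    write_metrics_csv(report, file.path(out_dir, "metrics"))
    utils::write.csv(model$finetune_trace,
                     file.path(out_dir, "finetune_trace.csv"), row.names = FALSE)
    pt <- data.frame(
      layer = rep(seq_along(model$pretrain_traces),
                  vapply(model$pretrain_traces, length, integer(1))),
      epoch = unlist(lapply(model$pretrain_traces, seq_along)),
      loss = unlist(model$pretrain_traces)
    )
    utils::write.csv(pt, file.path(out_dir, "pretrain_trace.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' @export
print.har_run <- function(x, ...) {
  cat("<har_run>", x$manifest$mode, "mode,", x$manifest$channels, "channels\n")
  cat(sprintf("  test accuracy (micro): %.2f%%\n",
              x$manifest$stages$evaluate$test_accuracy))
  invisible(x)
}

#' Sweep one configuration axis
#'
#' Re-runs the pipeline once per value of a single axis (all seeds and other
#' settings shared) and collects the overall test metrics in a long-format
#' table — the pattern behind iteration-count, learning-rate, depth,
#' resampling-method and sensor-ablation comparisons.
#'
#' @param config The base [run_config()].
#' @param axis One of `"finetune_epochs"`, `"pretrain_epochs"`,
#'   `"pretrain_lr"`, `"finetune_lr"`, `"hidden_layers"`,
#'   `"resample_method"`, `"channels"`.
#' @param values Vector of axis values. For `"hidden_layers"` an integer
#'   layer count (each layer keeps the first configured width); for the
#'   others, the literal setting.
#' @param quiet Suppress stage messages (default `TRUE`).
#' @return Data frame: `axis`, `value`, `accuracy`, `precision`, `recall`,
#'   `f1` (percent, micro-averaged), `n_test`.
#' @export
har_sweep <- function(config, axis, values, quiet = TRUE) {
  axis <- match.arg(axis, c(
    "finetune_epochs", "pretrain_epochs", "pretrain_lr", "finetune_lr",
    "hidden_layers", "resample_method", "channels"
  ))
  rows <- lapply(values, function(v) {
    cfg <- config
    switch(axis,
      finetune_epochs = { cfg$train$finetune_epochs <- as.integer(v) },
      pretrain_epochs = { cfg$train$pretrain_epochs <- as.integer(v) },
      pretrain_lr = { cfg$train$pretrain_lr <- as.numeric(v) },
      finetune_lr = { cfg$train$finetune_lr <- as.numeric(v) },
      hidden_layers = {
        cfg$train$hidden_sizes <- rep(cfg$train$hidden_sizes[1], as.integer(v))
      },
      resample_method = { cfg$plan$method <- as.character(v) },
      channels = { cfg$channels <- as.character(v) }
    )
    run <- har_run(cfg, quiet = quiet)
    ov <- run$report$overall[run$report$overall$mode == "micro", ]
    data.frame(
      axis = axis, value = as.character(v),
      accuracy = ov$accuracy, precision = ov$precision,
      recall = ov$recall, f1 = ov$f1,
      n_test = length(run$split$test)
    )
  })
  do.call(rbind, rows)
}
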