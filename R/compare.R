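# Desk-scale comparison harness: raw-waveform versus spectrogram pipelines
# across models, augmentation regimes and seeds.

raw_model_names <- c("elephant_caller_net", "mobilenet_v2", "yamnet_1d",
                     "rawnet_residual")
spec_model_names <- c("feature_cnn", "svm")

build_raw_model <- function(name, input_samples, n_classes, seed) {
  switch(name,
    elephant_caller_net = build_elephant_caller_net(
      input_samples = input_samples, n_classes = n_classes, seed = seed),
    mobilenet_v2 = build_mobilenet_v2_raw(
      n_classes = n_classes, input_samples = input_samples, seed = seed),
    yamnet_1d = build_yamnet_1d(
      n_classes = n_classes, input_samples = input_samples, seed = seed),
    rawnet_residual = build_rawnet_residual(
      n_classes = n_classes, input_samples = input_samples, seed = seed),
    abort(sprintf("unknown raw-pipeline model: %s", name),
          class = "tembo_validation_error")
  )
}

#' Run a raw-vs-spectrogram comparison experiment
#'
#' One row per (pipeline, model, regime, seed) combination: the manifest is
#' augmented under the regime (test split untouched), the model is trained
#' and evaluated, and accuracy plus complexity figures are reported.
#' Re-running with the same specification reproduces the table; the per-run
#' augmented training manifests are attached as attribute `"manifests"`.
#'
#' @param manifest A split manifest (see [stratified_split()]) whose clips
#'   are already standardized to a common duration.
#' @param models Model names: raw pipeline from `"elephant_caller_net"`,
#'   `"mobilenet_v2"`, `"yamnet_1d"`, `"rawnet_residual"`; spectrogram
#'   pipeline from `"feature_cnn"`, `"svm"`.
#' @param pipelines `"raw"`, `"spectrogram"`, or both.
#' @param regimes Augmentation regimes: `"none"`, `"approach1"`,
#'   `"approach2"`.
#' @param seeds Integer seeds; each adds one replicate per combination.
#' @param epochs Training epochs for the neural models.
#' @param learning_rates Named learning-rate overrides (defaults from
#'   [default_learning_rates()]).
#' @param train_batch Training batch size.
#' @param out_dir Scratch directory for augmented audio.
#' @return Tibble with columns pipeline, model, regime, seed, accuracy,
#'   parameter_count, serialized_size_bytes, flops_per_input, n_train.
#' @export
run_comparison <- function(manifest, models, pipelines = "raw",
                           regimes = "none", seeds = 1L, epochs = 10,
                           learning_rates = default_learning_rates(),
                           train_batch = 16,
                           out_dir = tempfile("tembo_cmp_")) {
  bad <- setdiff(pipelines, c("raw", "spectrogram"))
  if (length(bad) > 0) {
    abort(sprintf("unknown pipeline: %s", paste(bad, collapse = ", ")),
          class = "tembo_validation_error")
  }
  bad <- setdiff(models, c(raw_model_names, spec_model_names))
  if (length(bad) > 0) {
    abort(sprintf("unknown model: %s", paste(bad, collapse = ", ")),
          class = "tembo_validation_error")
  }
  grid <- tidyr::expand_grid(pipeline = pipelines, model = models,
                             regime = regimes, seed = seeds) |>
    dplyr::filter(
      (.data$pipeline == "raw" & .data$model %in% raw_model_names) |
        (.data$pipeline == "spectrogram" & .data$model %in% spec_model_names)
    )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifests <- list()
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    run_dir <- file.path(out_dir, sprintf("run%03d", i))
    aug <- apply_augmentation_plan(manifest, regime = g$regime,
                                   seed = g$seed, out_dir = run_dir)
    manifests[[sprintf("%s_%s_%s_s%d", g$pipeline, g$model, g$regime, g$seed)]] <<- aug
    tr <- aug[aug$split == "train", ]
    va <- aug[aug$split == "validation", ]
    te <- aug[aug$split == "test", ]
    if (g$pipeline == "raw") {
      train_set <- collect_waveforms(tr)
      val_set <- collect_waveforms(va)
      test_set <- collect_waveforms(te)
      model <- build_raw_model(g$model, ncol(train_set$x),
                               length(unique(manifest$label)), g$seed)
      lr <- learning_rates[[g$model]] %||% 5e-4
      fit <- train(model, train_set, val_set,
                   train_config(learning_rate = lr, train_batch = train_batch,
                                epochs = epochs, seed = g$seed))
      rep <- evaluate(fit, test_set)
      desc <- network_description(fit$model)
    } else {
      feats <- compute_features(dplyr::bind_rows(tr, va, te))
      is_tr <- feats$split == "train"
      norm <- fit_feature_normalizer(feats$features[is_tr])
      feats$features <- purrr::map(feats$features, normalize_feature_image,
                                   normalizer = norm)
      if (g$model == "svm") {
        clf <- fit_svm_spectral(feats$features[is_tr], feats$label[is_tr])
        pred <- predict(clf, feats$features[feats$split == "test"])
        rep <- eval_report(feats$label[feats$split == "test"], pred,
                           classes = sort(unique(manifest$label)))
        desc <- list(parameter_count = NA_real_,
                     serialized_size_bytes = NA_real_,
                     flops_per_input = NA_real_)
      } else {
        shape <- dim(feats$features[[1]]$stacked)
        xmat <- do.call(rbind, purrr::map(feats$features, flatten_feature_matrix))
        rownames(xmat) <- feats$clip_id
        model <- build_feature_cnn(length(unique(manifest$label)),
                                   input_shape = shape, seed = g$seed)
        sets <- split(seq_len(nrow(feats)), feats$split)
        mk <- function(ix) list(x = xmat[ix, , drop = FALSE], y = feats$label[ix])
        fit <- train(model, mk(sets$train), mk(sets$validation),
                     train_config(learning_rate = learning_rates[["feature_cnn"]] %||% 1e-3,
                                  train_batch = train_batch, epochs = epochs,
                                  seed = g$seed))
        rep <- evaluate(fit, mk(sets$test))
        desc <- network_description(fit$model)
      }
    }
    tibble(pipeline = g$pipeline, model = g$model, regime = g$regime,
           seed = g$seed, accuracy = rep$overall_accuracy,
           parameter_count = as.numeric(desc$parameter_count),
           serialized_size_bytes = as.numeric(desc$serialized_size_bytes),
           flops_per_input = as.numeric(desc$flops_per_input),
           n_train = nrow(tr))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "manifests") <- manifests
  out
}
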