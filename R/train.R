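# Training loop (Adam, per-epoch validation, best-checkpoint tracking) and
# the evaluation metric suite.

#' Training configuration
#'
#' Defaults mirror the reference configuration for the raw-audio models:
#' batch size 32 for training, 8 for validation, 60 epochs, Adam with a
#' per-model learning rate (see [default_learning_rates()]).
#'
#' @param learning_rate Positive learning rate.
#' @param train_batch,val_batch Batch sizes (>= 1).
#' @param epochs Number of epochs (default 60).
#' @param seed Integer seed controlling shuffling and dropout.
#' @param patience Early-stopping patience in epochs (`Inf` disables it;
#'   the default).
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 5e-4, train_batch = 32, val_batch = 8,
                         epochs = 60, seed = 1L, patience = Inf) {
  check_field(is_scalar_num(learning_rate) && learning_rate > 0,
              "learning_rate", "must be > 0")
  check_field(train_batch >= 1 && val_batch >= 1, "train_batch", "must be >= 1")
  check_field(epochs >= 1, "epochs", "must be >= 1")
  structure(list(learning_rate = learning_rate, train_batch = train_batch,
                 val_batch = val_batch, epochs = as.integer(epochs),
                 seed = as.integer(seed), patience = patience),
            class = "train_config")
}

#' Reference learning rates per raw-audio model
#' @return Named numeric vector.
#' @export
default_learning_rates <- function() {
  c(yamnet_1d = 0.0002, rawnet_residual = 0.00590, mobilenet_v2 = 0.000552,
    elephant_caller_net = 0.0005, feature_cnn = 0.001)
}

# Cross-entropy loss and gradient from logits (classes x n).
ce_loss_grad <- function(logits, y_idx) {
  n <- ncol(logits)
  m <- apply(logits, 2, max)
  sh <- sweep(logits, 2, m)
  lse <- m + log(colSums(exp(sh)))
  loss <- mean(lse - logits[cbind(y_idx, seq_len(n))])
  probs <- exp(sweep(logits, 2, lse))
  onehot <- matrix(0, nrow(logits), n)
  onehot[cbind(y_idx, seq_len(n))] <- 1
  list(loss = loss, grad = (probs - onehot) / n, probs = probs)
}

# Forward a dataset in evaluation mode, in batches; returns loss + accuracy.
eval_pass <- function(model, core_layers, x, y_idx, batch) {
  n <- nrow(x)
  total_loss <- 0
  correct <- 0
  for (s in seq(1, n, by = batch)) {
    ix <- s:min(n, s + batch - 1)
    xa <- model_input_array(model, x[ix, , drop = FALSE])
    logits <- nn_forward(core_layers, xa, training = FALSE)$y
    lg <- ce_loss_grad(logits, y_idx[ix])
    total_loss <- total_loss + lg$loss * length(ix)
    correct <- correct + sum(max.col(t(logits)) == y_idx[ix])
  }
  list(loss = total_loss / n, accuracy = correct / n)
}

#' Train a model
#'
#' Runs an Adam epoch loop with per-epoch validation, records learning
#' curves, and keeps the checkpoint with the best validation accuracy.
#' Fully deterministic for a given `(model, data, config)`.
#'
#' @param model A `tembo_model` (its softmax head is bypassed during
#'   training; the loss is computed on logits in the log domain).
#' @param train_set,val_set Lists with `x` (clips-in-rows waveform matrix)
#'   and `y` (character labels drawn from `model$classes`).
#' @param config A [train_config()].
#' @return A `tembo_fit`: list with `model` (best checkpoint), `curves`
#'   (tibble: epoch, train_loss, train_accuracy, val_loss, val_accuracy),
#'   `best_epoch`, `best_val_accuracy`, and `config`.
#' @export
train <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(model, "tembo_model"), inherits(config, "train_config"))
  y_tr <- match(as.character(train_set$y), model$classes)
  y_va <- match(as.character(val_set$y), model$classes)
  if (anyNA(y_tr) || anyNA(y_va)) {
    abort("labels outside the model's class set", class = "tembo_validation_error")
  }
  if (length(intersect(rownames(train_set$x) %||% character(0),
                       rownames(val_set$x) %||% character(0))) > 0) {
    abort("train and validation sets overlap", class = "tembo_validation_error")
  }
  has_softmax <- model$layers[[length(model$layers)]]$type == "softmax"
  core <- if (has_softmax) model$layers[-length(model$layers)] else model$layers
  n <- nrow(train_set$x)
  curves <- vector("list", config$epochs)
  best <- list(acc = -Inf, layers = NULL, epoch = 0L)
  withr::with_seed(config$seed, {
    adam <- adam_init(get_params(core))
    stale <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0
      for (s in seq(1, n, by = config$train_batch)) {
        ix <- ord[s:min(n, s + config$train_batch - 1)]
        xa <- model_input_array(model, train_set$x[ix, , drop = FALSE])
        fw <- nn_forward(core, xa, training = TRUE)
        core <- apply_state_updates(core, fw$state_update)
        lg <- ce_loss_grad(fw$y, y_tr[ix])
        if (!is.finite(lg$loss)) {
          abort(sprintf("non-finite loss (lr=%g, epoch=%d, batch starting at %d)",
                        config$learning_rate, epoch, s),
                class = "tembo_training_error")
        }
        ep_loss <- ep_loss + lg$loss * length(ix)
        ep_correct <- ep_correct + sum(max.col(t(lg$probs)) == y_tr[ix])
        bw <- nn_backward(core, fw$caches, lg$grad)
        upd <- adam_step(get_params(core), bw$grads, adam, config$learning_rate)
        adam <- upd$state
        core <- set_params(core, upd$params)
      }
      va <- eval_pass(model, core, val_set$x, y_va, config$val_batch)
      curves[[epoch]] <- tibble(
        epoch = epoch,
        train_loss = ep_loss / n, train_accuracy = ep_correct / n,
        val_loss = va$loss, val_accuracy = va$accuracy
      )
      if (va$accuracy > best$acc) {
        best <- list(acc = va$accuracy, layers = core, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
  })
  curves <- dplyr::bind_rows(curves)
  out_model <- model
  out_model$layers <- c(best$layers,
                        if (has_softmax) list(layer_softmax()) else NULL)
  structure(list(model = out_model, curves = curves, config = config,
                 best_epoch = best$epoch, best_val_accuracy = best$acc),
            class = "tembo_fit")
}

#' @export
print.tembo_fit <- function(x, ...) {
  cat(sprintf("<tembo_fit> %s: %d epochs, best val accuracy %.3f (epoch %d)\n",
              x$model$name, nrow(x$curves), x$best_val_accuracy, x$best_epoch))
  invisible(x)
}

#' @export
tidy.tembo_fit <- function(x, ...) x$curves

#' @export
glance.tembo_fit <- function(x, ...) {
  tibble(model = x$model$name, epochs = nrow(x$curves),
         best_epoch = x$best_epoch, best_val_accuracy = x$best_val_accuracy,
         final_train_loss = x$curves$train_loss[nrow(x$curves)],
         learning_rate = x$config$learning_rate)
}

#' @export
autoplot.tembo_fit <- function(object, ...) {
  df <- object$curves |>
    tidyr::pivot_longer(-"epoch", names_to = c("split", "metric"),
                        names_pattern = "(train|val)_(.*)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = sprintf("Learning curves: %s", object$model$name))
}

# ---- evaluation -------------------------------------------------------------

#' Build an evaluation report from truth and predictions
#'
#' @param truth,pred Character vectors of true and predicted labels.
#' @param classes Class levels (row/column order of the confusion matrix).
#' @return A `tembo_eval`: confusion matrix (rows = true class), overall
#'   accuracy, and per-class precision/recall/F1 (per-class accuracy is the
#'   recall of that class).
#' @export
eval_report <- function(truth, pred, classes = sort(unique(truth))) {
  cm <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  eval_report_from_confusion(unclass(matrix(cm, nrow = length(classes),
                                            dimnames = list(classes, classes))))
}

#' Build an evaluation report from a confusion matrix
#'
#' @param cm Square integer matrix, rows = true class, columns = predicted.
#' @return A `tembo_eval` object.
#' @export
eval_report_from_confusion <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  classes <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  precision <- ifelse(predicted > 0, tp / predicted, NA_real_)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(
    confusion_matrix = cm,
    overall_accuracy = sum(tp) / sum(cm),
    per_class = tibble(class = classes, support = as.integer(unname(support)),
                       accuracy = unname(recall), precision = unname(precision),
                       recall = unname(recall), f1 = unname(f1))
  ), class = "tembo_eval")
}

#' Evaluate a trained model on a labelled test set
#'
#' @param model A `tembo_model` (or `tembo_fit`, whose best checkpoint is
#'   used).
#' @param test_set List with `x` (waveform matrix) and `y` (labels).
#' @return A `tembo_eval` report.
#' @export
evaluate <- function(model, test_set) {
  if (inherits(model, "tembo_fit")) model <- model$model
  if (is.null(test_set$x) || nrow(test_set$x) == 0) {
    abort("empty test set", class = "tembo_validation_error")
  }
  pred <- predict(model, test_set$x, type = "class")
  eval_report(as.character(test_set$y), pred, classes = model$classes)
}

#' @export
print.tembo_eval <- function(x, ...) {
  cat(sprintf("<tembo_eval> overall accuracy %.3f\n", x$overall_accuracy))
  print(x$confusion_matrix)
  invisible(x)
}

#' @export
tidy.tembo_eval <- function(x, ...) x$per_class

#' @export
glance.tembo_eval <- function(x, ...) {
  tibble(overall_accuracy = x$overall_accuracy,
         macro_f1 = mean(x$per_class$f1, na.rm = TRUE),
         n = sum(x$confusion_matrix))
}

#' @export
autoplot.tembo_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion_matrix))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = "Confusion matrix", x = "predicted", y = "true")
}

#' Load a manifest's waveforms into a training matrix
#'
#' @param manifest Manifest tibble with `path` and `label`.
#' @param target_sr Optional resampling rate.
#' @return List with `x` (clips-in-rows matrix, rownames = clip ids) and `y`
#'   (character labels).
#' @export
collect_waveforms <- function(manifest, target_sr = NULL) {
  clips <- purrr::map(seq_len(nrow(manifest)), function(i) {
    load_audio(manifest$path[i], target_sr = target_sr)$samples
  })
  len <- unique(lengths(clips))
  if (length(len) != 1) {
    abort("clips have differing lengths; run prepare_clips() first",
          class = "tembo_validation_error")
  }
  x <- do.call(rbind, clips)
  rownames(x) <- manifest$clip_id
  list(x = x, y = manifest$label)
}
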