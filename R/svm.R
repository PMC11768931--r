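# Nonlinear-kernel SVM over flattened spectrogram feature images.

#' Fit an RBF-kernel SVM on spectral features
#'
#' One-vs-rest radial-basis-function SVM (libsvm via e1071) over flattened
#' feature images. Deterministic for fixed inputs; invariant to training
#' order.
#'
#' @param x Numeric feature matrix, samples in rows (e.g. flattened stacked
#'   MFCC + chroma images), or a list of `feature_image`s.
#' @param labels Class labels (>= 2 distinct classes required).
#' @param cost Soft-margin cost parameter.
#' @param gamma RBF kernel width; defaults to `1/ncol(x)`.
#' @return A `tembo_svm` classifier.
#' @export
fit_svm_spectral <- function(x, labels, cost = 1, gamma = NULL) {
  if (is.list(x) && !is.matrix(x)) {
    x <- do.call(rbind, purrr::map(x, flatten_feature_matrix))
  }
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    abort("need at least two classes to fit an SVM",
          class = "tembo_validation_error")
  }
  gamma <- gamma %||% (1 / ncol(x))
  fit <- e1071::svm(x = x, y = factor(labels), kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, classes = levels(factor(labels)), gamma = gamma,
                 cost = cost),
            class = "tembo_svm")
}

#' @export
predict.tembo_svm <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.matrix(newdata)) {
    newdata <- do.call(rbind, purrr::map(newdata, flatten_feature_matrix))
  }
  as.character(predict(object$fit, newdata))
}

#' @export
print.tembo_svm <- function(x, ...) {
  cat(sprintf("<tembo_svm> RBF kernel, %d support vectors, classes: %s\n",
              x$fit$tot.nSV, paste(x$classes, collapse = ", ")))
  invisible(x)
}
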