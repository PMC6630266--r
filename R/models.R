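#' Classical baseline classifiers
#'
#' Wraps established implementations of the three classical comparators —
#' radial-basis-function SVM ([e1071::svm()]), linear discriminant analysis
#' ([MASS::lda()]) and k-nearest neighbours ([class::knn()]) — behind the
#' same fit/predict contract as the convolutional models. Features are
#' flattened per segment before fitting.
#'
#' @param kind `"svm_rbf"`, `"lda"` or `"knn"`.
#' @param features numeric matrix, one row per segment.
#' @param labels factor/character gesture labels.
#' @param k neighbours for KNN (default 5).
#' @return object of class `semg_baseline`.
#' @export
baseline_classifier <- function(kind = c("svm_rbf", "lda", "knn"), features,
                                labels, k = 5L) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  labels <- factor(as.character(labels), levels = gesture_classes())
  if (length(unique(labels)) < 2L) stop("need at least two classes to fit")
  fit <- switch(kind,
    svm_rbf = e1071::svm(x = features, y = droplevels(labels),
                         kernel = "radial"),
    lda = MASS::lda(x = features, grouping = droplevels(labels)),
    knn = list(train = features, labels = droplevels(labels),
               k = as.integer(k)))
  structure(list(kind = kind, fit = fit, levels = levels(droplevels(labels))),
            class = "semg_baseline")
}

#' @export
predict.semg_baseline <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  pred <- switch(object$kind,
    svm_rbf = as.character(stats::predict(object$fit, newdata)),
    lda = as.character(stats::predict(object$fit, newdata)$class),
    knn = as.character(class::knn(object$fit$train, newdata,
                                  object$fit$labels, k = object$fit$k)))
  factor(pred, levels = gesture_classes())
}

#' Predict gestures for a set of segments with a trained CNN
#'
#' Each segment tensor is cut into fixed-height blocks ([tensor_blocks()]),
#' the network scores every block, and the segment-level probability vector
#' is the mean of its block probabilities (dropout is off at inference, so
#' prediction is deterministic). The predicted gesture is the argmax.
#'
#' @param net a trained `dpc_cnn`.
#' @param tensors list of segment arrays `n_frames x k x channels`.
#' @param height,block_step block geometry passed to [tensor_blocks()].
#' @return list with `probs` (matrix `n_segments x 4`) and `class` (factor).
#' @export
predict_segments <- function(net, tensors, height = net$input_shape[1],
                             block_step = 4L) {
  probs <- matrix(NA_real_, length(tensors), length(net$classes),
                  dimnames = list(NULL, net$classes))
  for (i in seq_along(tensors)) {
    blocks <- tensor_blocks(tensors[[i]], height = height,
                            block_step = block_step)
    x <- array(unlist(blocks),
               dim = c(dim(blocks[[1]]), length(blocks)))
    p <- cnn_predict(net, x)
    probs[i, ] <- colMeans(p)
  }
  cls <- factor(net$classes[max.col(probs, ties.method = "first")],
                levels = gesture_classes())
  list(probs = probs, class = cls)
}

#' Stack segment tensors into a network training array
#'
#' Cuts every segment into blocks and returns the stacked input array plus
#' the per-block labels and the originating segment index.
#'
#' @param tensors list of segment arrays `n_frames x k x channels`.
#' @param labels gesture label per segment.
#' @param height,block_step block geometry, see [tensor_blocks()].
#' @return list: `x` (array `height x k x channels x n_blocks`), `y`
#'   (character), `segment` (integer index).
#' @export
stack_blocks <- function(tensors, labels, height = 8L, block_step = 4L) {
  stopifnot(length(tensors) == length(labels))
  xs <- list(); ys <- character(0); seg <- integer(0)
  for (i in seq_along(tensors)) {
    blocks <- tensor_blocks(tensors[[i]], height = height,
                            block_step = block_step)
    xs <- c(xs, blocks)
    ys <- c(ys, rep(as.character(labels[i]), length(blocks)))
    seg <- c(seg, rep(i, length(blocks)))
  }
  x <- array(unlist(xs), dim = c(dim(xs[[1]]), length(xs)))
  list(x = x, y = ys, segment = seg)
}
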