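#' Pluggable base classifier
#'
#' All learning stages (pipelines, wrapper feature selection, self-training,
#' location detection) use a classifier behind this small interface, so the
#' learner can be swapped without touching the pipeline logic. The default is
#' a probability random forest: a stable choice for windowed inertial-sensor
#' features that trains quickly and needs little tuning.
#'
#' @param num_trees Number of trees for the default random forest.
#' @param fit Function `(x, y, seed)` returning a model; `x` a data frame of
#'   features, `y` an integer class vector.
#' @param predict_prob Function `(model, x)` returning a rows x classes
#'   probability matrix with one column per class level seen at fit time.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(num_trees = 200L, fit = NULL, predict_prob = NULL) {
  if (is.null(fit) != is.null(predict_prob)) {
    abort("provide both fit and predict_prob, or neither")
  }
  structure(
    list(num_trees = as.integer(num_trees), fit = fit,
         predict_prob = predict_prob),
    class = "classifier_spec"
  )
}

#' Fit the base classifier
#'
#' @param spec A [classifier_spec()].
#' @param x Data frame (or tibble) of feature columns.
#' @param y Integer class labels.
#' @param seed Seed for the learner's internal randomness.
#' @return A `fitted_classifier` holding the model and its class levels.
#' @export
clf_fit <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.data.frame(x)
  levels <- sort(unique(as.integer(y)))
  if (length(levels) < 1) abort("no training labels")
  if (!is.null(spec$fit)) {
    model <- spec$fit(x, as.integer(y), seed)
  } else {
    model <- ranger::ranger(
      x = x, y = factor(as.integer(y), levels = levels),
      num.trees = spec$num_trees, probability = TRUE,
      seed = seed, num.threads = 1
    )
  }
  structure(list(spec = spec, model = model, levels = levels),
            class = "fitted_classifier")
}

#' Predict labels and class probabilities
#'
#' @param fit A `fitted_classifier`.
#' @param x Data frame of the same feature columns used at fit time.
#' @return A list with `labels` (integer codes; argmax with ties broken
#'   toward the lower code) and `probs` (rows x classes matrix, columns named
#'   by class code).
#' @export
clf_predict <- function(fit, x) {
  stopifnot(inherits(fit, "fitted_classifier"))
  x <- as.data.frame(x)
  if (!is.null(fit$spec$predict_prob)) {
    probs <- fit$spec$predict_prob(fit$model, x)
  } else {
    probs <- stats::predict(fit$model, data = x, num.threads = 1)$predictions
  }
  probs <- as.matrix(probs)
  colnames(probs) <- as.character(fit$levels)
  labels <- fit$levels[max.col(probs, ties.method = "first")]
  list(labels = as.integer(labels), probs = probs)
}
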