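#' Instance-selection strategy for self-training
#'
#' Five predicates decide which pseudo-labeled instances are added to the
#' labeled pool, based on the classifier's confidence `p` (the maximum class
#' probability) and on whether the classifier and the HMM-smoothed
#' prediction agree:
#'
#' * `S1`: `p > thr` (confidence only; the HMM-free strategy)
#' * `S2`: `p > thr` and classifier and HMM agree
#' * `S3`: `p > thr` and classifier and HMM disagree
#' * `S4`: `p < thr` and classifier and HMM disagree
#' * `S5`: (`p > thr` and agree) or (`p < thr` and disagree)
#'
#' Comparisons are strict. The assigned label comes from `label_source`:
#' the classifier's prediction (`"CLF"`) or the HMM-smoothed one (`"HMM"`).
#'
#' @param predicate One of `"S1"` ... `"S5"`.
#' @param thr Probability threshold in \[0, 1\].
#' @param label_source `"CLF"` or `"HMM"`.
#' @param rounds Number of self-training rounds (default 1).
#' @return An object of class `ssl_strategy`.
#' @export
ssl_strategy <- function(predicate = c("S1", "S2", "S3", "S4", "S5"),
                         thr = 0.5, label_source = c("CLF", "HMM"),
                         rounds = 1L) {
  predicate <- match.arg(predicate)
  label_source <- match.arg(label_source)
  if (thr < 0 || thr > 1) abort("thr must be in [0, 1]")
  if (rounds < 1) abort("rounds must be >= 1")
  structure(list(predicate = predicate, thr = thr,
                 label_source = label_source, rounds = as.integer(rounds)),
            class = "ssl_strategy")
}

#' Select pseudo-labeled instances under a strategy
#'
#' @param probs Per-instance maximum class probability.
#' @param clf_labels Classifier-predicted labels.
#' @param hmm_labels HMM-smoothed labels (may be `NULL` only for `S1`).
#' @param strategy An [ssl_strategy()].
#' @return A list with `index` (selected positions, satisfying the predicate
#'   exactly) and `labels` (the labels to assign, from the strategy's label
#'   source).
#' @export
select_instances <- function(probs, clf_labels, hmm_labels = NULL,
                             strategy = ssl_strategy()) {
  stopifnot(inherits(strategy, "ssl_strategy"))
  n <- length(probs)
  if (length(clf_labels) != n) abort("probs and clf_labels must align")
  if (is.null(hmm_labels)) {
    if (strategy$predicate != "S1") {
      abort(sprintf("strategy %s requires hmm_labels", strategy$predicate))
    }
    if (strategy$label_source == "HMM") {
      abort("label_source HMM requires hmm_labels")
    }
  } else if (length(hmm_labels) != n) {
    abort("probs and hmm_labels must align")
  }
  thr <- strategy$thr
  agree <- if (!is.null(hmm_labels)) clf_labels == hmm_labels else NULL
  sel <- switch(
    strategy$predicate,
    S1 = probs > thr,
    S2 = probs > thr & agree,
    S3 = probs > thr & !agree,
    S4 = probs < thr & !agree,
    S5 = (probs > thr & agree) | (probs < thr & !agree)
  )
  idx <- which(sel)
  labels <- switch(strategy$label_source,
                   CLF = clf_labels[idx],
                   HMM = hmm_labels[idx])
  list(index = idx, labels = as.integer(labels))
}

#' Self-training semi-supervised learning
#'
#' Each round: fit the base classifier on the current labeled pool, predict
#' the unlabeled set, optionally smooth those predictions per ordered chain
#' with the supplied HMM, select instances under the strategy, and append
#' them to the pool with their assigned pseudo-labels. After the final round
#' the model is refit on the extended pool. Original labeled instances are
#' never relabeled or dropped. If nothing is selected in the first round the
#' base model is returned with a warning flag (not an error); if one class
#' exceeds 80% of the selections a degeneracy warning is flagged.
#'
#' @param labeled,unlabeled Feature tables sharing feature columns;
#'   `labeled$label` supplies the supervision, the unlabeled labels (if any)
#'   are ignored.
#' @param strategy An [ssl_strategy()].
#' @param classifier A [classifier_spec()].
#' @param hmm An optional [hmm_params()] enabling HMM-aware strategies.
#' @param chains Optional list of index vectors into `unlabeled` giving the
#'   locally ordered chains; smoothing is applied within chains only and
#'   never across chain boundaries. Default: one chain covering the set in
#'   row order.
#' @param features Feature columns to use (default all).
#' @param seed Seed for all classifier fits.
#' @return An object of class `ssl_result`: `model` (fitted classifier),
#'   `predictions` (final predictions on the unlabeled set),
#'   `selected` (tibble: round, class, n), `n_selected`, `warnings`
#'   (character vector of flags).
#' @export
self_train <- function(labeled, unlabeled, strategy = ssl_strategy(),
                       classifier = classifier_spec(), hmm = NULL,
                       chains = NULL, features = NULL, seed = 1L) {
  stopifnot(inherits(strategy, "ssl_strategy"))
  features <- features %||% intersect(feature_names(labeled),
                                      feature_names(unlabeled))
  if (is.null(hmm) && strategy$predicate != "S1") {
    abort(sprintf("strategy %s requires an HMM", strategy$predicate))
  }
  chains <- chains %||% list(seq_len(nrow(unlabeled)))
  pool_x <- labeled[, features, drop = FALSE]
  pool_y <- labeled$label
  flags <- character(0)
  sel_log <- list()
  base_fit <- clf_fit(classifier, pool_x, pool_y, seed)
  fit <- base_fit
  for (round in seq_len(strategy$rounds)) {
    pred <- clf_predict(fit, unlabeled[, features, drop = FALSE])
    pmax_ <- apply(pred$probs, 1, max)
    hmm_labels <- NULL
    if (!is.null(hmm)) {
      hmm_labels <- integer(nrow(unlabeled))
      for (ch in chains) {
        hmm_labels[ch] <- smooth_predictions(pred$labels[ch], hmm)
      }
    }
    sel <- select_instances(pmax_, pred$labels, hmm_labels, strategy)
    if (length(sel$index) == 0) {
      if (round == 1) flags <- c(flags, "no_selection_round_1")
      break
    }
    tab <- table(sel$labels)
    if (max(tab) / length(sel$labels) > 0.8) {
      flags <- c(flags, sprintf("degenerate_selection_round_%d", round))
    }
    sel_log[[round]] <- tibble::tibble(
      round = round, class = as.integer(names(tab)), n = as.integer(tab)
    )
    pool_x <- bind_rows(pool_x, unlabeled[sel$index, features, drop = FALSE])
    pool_y <- c(pool_y, sel$labels)
    fit <- clf_fit(classifier, pool_x, pool_y, seed)
  }
  final_pred <- clf_predict(fit, unlabeled[, features, drop = FALSE])
  structure(
    list(model = fit, base_model = base_fit,
         predictions = final_pred$labels, probs = final_pred$probs,
         selected = bind_rows(sel_log),
         n_selected = length(pool_y) - nrow(labeled),
         warnings = flags, strategy = strategy, features = features),
    class = "ssl_result"
  )
}

#' @export
print.ssl_result <- function(x, ...) {
  cat(sprintf("<ssl_result> %s/%s thr=%g: %d instances added%s\n",
              x$strategy$predicate, x$strategy$label_source, x$strategy$thr,
              x$n_selected,
              if (length(x$warnings)) paste0(" [", paste(x$warnings, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Sweep self-training strategies over a threshold grid
#'
#' Runs [self_train()] for every combination of predicate, label source and
#' threshold and reports the resulting macro F1 on the unlabeled set against
#' supplied reference labels — the benchmark grid for choosing a selection
#' strategy.
#'
#' @inheritParams self_train
#' @param truth True labels of the unlabeled set (evaluation only).
#' @param thresholds Probability thresholds to sweep.
#' @param predicates,label_sources Grid axes; HMM-dependent combinations are
#'   skipped when `hmm` is `NULL`.
#' @return A tibble with columns `predicate`, `label_source`, `thr`,
#'   `macro_f1`, `n_selected`.
#' @export
sweep_ssl_strategies <- function(labeled, unlabeled, truth,
                                 classifier = classifier_spec(), hmm = NULL,
                                 chains = NULL,
                                 thresholds = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                 predicates = c("S1", "S2", "S3", "S4", "S5"),
                                 label_sources = c("CLF", "HMM"),
                                 seed = 1L) {
  grid <- expand.grid(predicate = predicates, label_source = label_sources,
                      thr = thresholds, stringsAsFactors = FALSE)
  valid <- !(is.null(hmm) & (grid$predicate != "S1" | grid$label_source == "HMM"))
  grid <- grid[valid, , drop = FALSE]
  purrr::pmap_dfr(grid, function(predicate, label_source, thr) {
    res <- self_train(labeled, unlabeled,
                      ssl_strategy(predicate, thr, label_source),
                      classifier, hmm, chains, seed = seed)
    tibble::tibble(
      predicate = predicate, label_source = label_source, thr = thr,
      macro_f1 = macro_f1(confusion_matrix(truth, res$predictions)),
      n_selected = res$n_selected
    )
  })
}
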