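#' Rank features by mutual information with the label
#'
#' Estimates the mutual information (in nats) between each feature and the
#' activity label with a plug-in estimator after equal-frequency
#' discretisation of the feature, and returns the features in descending MI
#' order (name order on ties). Higher MI means stronger statistical
#' dependency between feature and label.
#'
#' @param ft A feature table ([extract_features()]).
#' @param bins Number of equal-frequency bins used to discretise features.
#' @return A tibble with columns `feature` and `mi`, in non-increasing `mi`
#'   order.
#' @export
rank_mutual_information <- function(ft, bins = 20L) {
  y <- ft$label
  if (length(unique(y)) < 2) abort("label must have at least 2 classes")
  fnames <- feature_names(ft)
  mi <- vapply(fnames, function(f) {
    discrete_mutual_information(discretise_equal_frequency(ft[[f]], bins), y)
  }, numeric(1))
  tibble::tibble(feature = fnames, mi = mi) %>%
    arrange(desc(.data$mi), .data$feature)
}

discretise_equal_frequency <- function(x, bins) {
  ux <- unique(x)
  # discrete-valued features keep their own levels (quantile breaks would
  # merge distinct values and understate the MI)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(qs) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

discrete_mutual_information <- function(x, y) {
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  idx <- joint > 0
  outer_p <- outer(px, py)
  sum(joint[idx] * log(joint[idx] / outer_p[idx]))
}

#' Entropy of a discrete label vector (nats)
#'
#' @param y Vector of class labels.
#' @return Shannon entropy in nats.
#' @export
label_entropy <- function(y) {
  p <- table(y) / length(y)
  -sum(p[p > 0] * log(p[p > 0]))
}

#' Drop the lower-MI member of highly correlated feature pairs
#'
#' Walks the features in MI order; a feature is kept only if its absolute
#' Pearson correlation with every already-kept feature is at most
#' `r_threshold`. Within any correlated group the highest-MI member
#' therefore survives.
#'
#' @param ranked Output of [rank_mutual_information()].
#' @param ft The feature table the ranking was computed on.
#' @param r_threshold Correlation threshold in (0, 1].
#' @return Character vector of retained feature names (in MI order), with a
#'   `pruned` attribute: a tibble of dropped features, the kept feature that
#'   triggered the drop, and the offending correlation.
#' @export
prune_correlated <- function(ranked, ft, r_threshold = 0.9) {
  if (r_threshold <= 0 || r_threshold > 1) {
    abort("r_threshold must be in (0, 1]")
  }
  x <- as.matrix(ft[, ranked$feature, drop = FALSE])
  # guard: zero-variance columns correlate with nothing
  sds <- apply(x, 2, sd_or_zero)
  cors <- suppressWarnings(abs(cor(x)))
  cors[!is.finite(cors)] <- 0
  kept <- character(0)
  audit <- list()
  for (f in ranked$feature) {
    if (length(kept) == 0) {
      kept <- f
      next
    }
    r <- cors[f, kept]
    if (all(r <= r_threshold)) {
      kept <- c(kept, f)
    } else {
      j <- which.max(r)
      audit[[length(audit) + 1]] <- tibble::tibble(
        dropped = f, kept = kept[j], r = unname(r[j])
      )
    }
  }
  structure(kept, pruned = bind_rows(audit))
}

#' Greedy-wrapper feature selection
#'
#' Starting from the best-ranked feature, walks the candidate list in order
#' and keeps a feature if and only if adding it strictly increases the
#' classification accuracy on the validation table. Each decision is
#' recorded in an audit trail. Because only strict improvements are kept,
#' the final validation accuracy is at least that of the first feature
#' alone, and the recorded accuracy after each accepted feature is strictly
#' increasing.
#'
#' @param train,valid Feature tables sharing the candidate columns.
#' @param candidates Ordered character vector of candidate feature names
#'   (typically MI order after correlation pruning).
#' @param classifier A [classifier_spec()].
#' @param seed Seed for each classifier fit.
#' @return An object of class `selection_result`: list with `selected`
#'   (character vector) and `audit` (tibble with `feature`, `accuracy`,
#'   `kept`).
#' @export
greedy_wrapper <- function(train, valid, candidates,
                           classifier = classifier_spec(), seed = 1L) {
  if (length(candidates) == 0) abort("no candidate features")
  missing <- setdiff(candidates, intersect(names(train), names(valid)))
  if (length(missing) > 0) {
    abort(sprintf("candidates absent from train/valid: %s",
                  paste(head(missing, 3), collapse = ", ")))
  }
  acc_with <- function(feats) {
    fit <- clf_fit(classifier, train[, feats, drop = FALSE], train$label, seed)
    mean(clf_predict(fit, valid[, feats, drop = FALSE])$labels == valid$label)
  }
  selected <- candidates[1]
  best_acc <- acc_with(selected)
  audit <- list(tibble::tibble(feature = candidates[1], accuracy = best_acc,
                               kept = TRUE))
  for (f in candidates[-1]) {
    acc <- acc_with(c(selected, f))
    kept <- acc > best_acc
    if (kept) {
      selected <- c(selected, f)
      best_acc <- acc
    }
    audit[[length(audit) + 1]] <- tibble::tibble(feature = f, accuracy = acc,
                                                 kept = kept)
  }
  structure(list(selected = selected, audit = bind_rows(audit)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features selected of %d candidates\n",
              length(x$selected), nrow(x$audit)))
  invisible(x)
}

#' Run the full three-step feature selection
#'
#' MI ranking, correlation pruning, then the greedy wrapper, evaluated
#' against a validation table to which the features are adapted.
#'
#' @inheritParams greedy_wrapper
#' @inheritParams prune_correlated
#' @param max_candidates Cap on the number of pruned candidates handed to the
#'   wrapper (wrapper cost is one model fit per candidate).
#' @param bins MI discretisation bins.
#' @return A `selection_result` (see [greedy_wrapper()]), with the MI ranking
#'   and pruning audit attached as `ranking` and `pruned`.
#' @export
select_features <- function(train, valid, r_threshold = 0.9,
                            classifier = classifier_spec(), seed = 1L,
                            max_candidates = 50L, bins = 20L) {
  ranked <- rank_mutual_information(train, bins = bins)
  pruned <- prune_correlated(ranked, train, r_threshold)
  candidates <- head(as.character(pruned), max_candidates)
  res <- greedy_wrapper(train, valid, candidates, classifier, seed)
  res$ranking <- ranked
  res$pruned <- attr(pruned, "pruned")
  res
}

#' Quarter-fold domain-adaptive feature selection
#'
#' Splits the validation-style table into four contiguous quarters and runs
#' the three-step selection once per quarter: the classifier trains on the
#' training pool plus the other three quarters and adapts to the held
#' quarter. The final set is the intersection of the four per-fold
#' selections (features that transfer under every fold), or their union when
#' `scheme = "union"` (the per-cluster variant, where coverage matters more
#' than unanimity).
#'
#' @param train_pool Feature table always available for training.
#' @param valid_set Feature table split into 4 contiguous quarters.
#' @param scheme `"intersection"` or `"union"`.
#' @inheritParams select_features
#' @return Character vector of selected features. If the intersection is
#'   empty a zero-length vector is returned with attribute `empty = TRUE`
#'   and a warning (callers fall back to the full set). Per-fold selections
#'   are attached as attribute `folds`.
#' @export
adapt_across_quarters <- function(train_pool, valid_set,
                                  scheme = c("intersection", "union"),
                                  r_threshold = 0.9,
                                  classifier = classifier_spec(), seed = 1L,
                                  max_candidates = 50L) {
  scheme <- match.arg(scheme)
  n <- nrow(valid_set)
  if (n < 4) abort("validation set must allow 4 quarters")
  quarter <- ceiling(seq_len(n) / (n / 4))
  quarter[quarter > 4] <- 4L
  folds <- lapply(1:4, function(q) {
    train <- bind_rows(train_pool, valid_set[quarter != q, , drop = FALSE])
    valid <- valid_set[quarter == q, , drop = FALSE]
    select_features(train, valid, r_threshold, classifier,
                    seed = seed + q, max_candidates = max_candidates)$selected
  })
  selected <- if (scheme == "intersection") {
    Reduce(intersect, folds)
  } else {
    Reduce(union, folds)
  }
  if (length(selected) == 0) {
    warn("quarter-fold selections have empty intersection; returning empty set")
    return(structure(character(0), empty = TRUE, folds = folds))
  }
  structure(selected, empty = FALSE, folds = folds)
}
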