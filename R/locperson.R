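#' Detect dynamic (walking/running) windows
#'
#' Phone placement is only visible in the signal while the wearer moves, so
#' location detection first gates on the dynamic activities: a binary
#' classifier separates walking/running windows from everything else (the
#' argmax class is used, with no custom operating point).
#'
#' @param ft Feature table to flag.
#' @param model A fitted dynamic/other classifier from
#'   [fit_dynamic_detector()].
#' @return Logical vector: `TRUE` for windows flagged walking/running.
#' @export
detect_dynamic <- function(ft, model) {
  if (!inherits(model, "fitted_classifier")) {
    abort("model must be a fitted_classifier (see fit_dynamic_detector())")
  }
  pred <- clf_predict(model, ft[, model$feature_columns %||% feature_names(ft), drop = FALSE])
  pred$labels == 2L
}

#' @rdname detect_dynamic
#' @param train_ft Labeled (8-class) feature table; labels are mapped to
#'   dynamic = walk/run vs other before fitting.
#' @param classifier A [classifier_spec()].
#' @param seed Fit seed.
#' @export
fit_dynamic_detector <- function(train_ft, classifier = classifier_spec(),
                                 seed = 1L) {
  y <- ifelse(train_ft$label %in% c(2L, 3L), 2L, 1L) # 2 = walking/running
  fit <- clf_fit(classifier, train_ft[, feature_names(train_ft), drop = FALSE],
                 y, seed)
  fit$feature_columns <- feature_names(train_ft)
  fit
}

#' Aggregate per-window location votes into one location decision
#'
#' @param counts Named integer vector of per-location window counts.
#' @return The plurality location name (ties toward the first name).
#' @examples
#' aggregate_location(c(bag = 95, hand = 2430, hips = 12901, torso = 38))
#' @export
aggregate_location <- function(counts) {
  if (length(counts) == 0 || sum(counts) == 0) return(NA_character_)
  names(counts)[which.max(counts)]
}

#' Detect the phone location from dynamic-flagged windows
#'
#' Predicts a location (bag, hand, hips, torso) for every dynamic-flagged
#' window with the supplied location model and aggregates by plurality. The
#' aggregate decision is invariant to window order. With zero dynamic
#' windows an explicit undecidable result is returned rather than an error.
#'
#' @param ft Feature table (all windows).
#' @param dynamic_flags Logical vector from [detect_dynamic()].
#' @param model A fitted location classifier from [fit_location_detector()].
#' @return An object of class `location_decision`: list with `per_window`
#'   (tibble: window_id, location or NA for non-dynamic windows), `counts`
#'   (named vector over locations), `aggregate` (location name or NA), and
#'   `n_dynamic`.
#' @export
detect_location <- function(ft, dynamic_flags, model) {
  stopifnot(length(dynamic_flags) == nrow(ft))
  locs <- c("bag", "hand", "hips", "torso")
  per_window <- rep(NA_character_, nrow(ft))
  if (any(dynamic_flags)) {
    pred <- clf_predict(model, ft[dynamic_flags,
                                  model$feature_columns %||% feature_names(ft),
                                  drop = FALSE])
    per_window[dynamic_flags] <- locs[pred$labels]
  }
  counts <- vapply(locs, function(l) sum(per_window == l, na.rm = TRUE),
                   integer(1))
  structure(
    list(
      per_window = tibble::tibble(window_id = ft$window_id,
                                  location = per_window),
      counts = counts,
      aggregate = aggregate_location(counts),
      n_dynamic = sum(dynamic_flags)
    ),
    class = "location_decision"
  )
}

#' @rdname detect_location
#' @param train_ft Feature table with a `location` column restricted to (or
#'   filtered for) dynamic windows for training.
#' @param classifier A [classifier_spec()].
#' @param seed Fit seed.
#' @export
fit_location_detector <- function(train_ft, classifier = classifier_spec(),
                                  seed = 1L) {
  locs <- c("bag", "hand", "hips", "torso")
  y <- match(train_ft$location, locs)
  if (any(is.na(y))) abort("location column must be bag/hand/hips/torso")
  fit <- clf_fit(classifier, train_ft[, feature_names(train_ft), drop = FALSE],
                 y, seed)
  fit$feature_columns <- feature_names(train_ft)
  fit
}

#' @export
print.location_decision <- function(x, ...) {
  cat(sprintf("<location_decision> %s (%d dynamic windows: %s)\n",
              x$aggregate %||% "undecidable", x$n_dynamic,
              paste(sprintf("%s=%d", names(x$counts), x$counts),
                    collapse = ", ")))
  invisible(x)
}

#' Cluster windows into two putative wearers
#'
#' K-means with k = 2 (two test users known a priori) and 10 restarts under
#' a fixed seed. The average silhouette width is reported as a separation
#' diagnostic. When ordered chains are supplied, each chain's windows are
#' reassigned to the chain-majority cluster, so consecutive windows always
#' share a cluster.
#'
#' @param ft Feature table.
#' @param features Feature subset to cluster on (default all; see
#'   [importance_subset()] for a user-discriminative subset).
#' @param chains Optional list of index vectors (ordered chains).
#' @param seed Seed for the k-means restarts.
#' @return An object of class `cluster_assignment`: tibble `assignment`
#'   (window_id, cluster, smoothed cluster), `silhouette` (mean width),
#'   `smoothed` (logical).
#' @export
cluster_persons <- function(ft, features = NULL, chains = NULL, seed = 1L) {
  features <- features %||% feature_names(ft)
  x <- scale(as.matrix(ft[, features, drop = FALSE]))
  x[!is.finite(x)] <- 0
  if (nrow(unique(x)) < 2) abort("need at least 2 distinct points to cluster")
  km <- with_seed(seed, kmeans(x, centers = 2, nstart = 10))
  sil <- cluster::silhouette(km$cluster, stats::dist(x))
  smoothed <- km$cluster
  if (!is.null(chains)) {
    for (ch in chains) {
      tab <- tabulate(km$cluster[ch], nbins = 2)
      smoothed[ch] <- which.max(tab)
    }
  }
  structure(
    list(
      assignment = tibble::tibble(
        window_id = ft$window_id, cluster = km$cluster, smoothed = smoothed
      ),
      silhouette = mean(sil[, "sil_width"]),
      smoothed = !is.null(chains)
    ),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> sizes %s, silhouette %.3f%s\n",
              paste(table(x$assignment$cluster), collapse = "/"),
              x$silhouette, if (x$smoothed) " (chain-smoothed)" else ""))
  invisible(x)
}

#' Features that discriminate one data pool from another
#'
#' Fits the classifier to separate pool membership (a binary task: does a
#' window come from the training pool or the validation pool?) and returns
#' the top features by impurity importance. Features that separate the pools
#' are the ones that encode the domain difference (for example the wearer's
#' identity), and are therefore good clustering features. When the pools
#' contain several phone locations the selection is run per location and the
#' union is returned.
#'
#' @param train_pool,valid_pool Feature tables.
#' @param n_top Number of features per location.
#' @param classifier A [classifier_spec()] (must be the default random
#'   forest or another learner exposing `variable.importance`).
#' @param seed Fit seed.
#' @return Character vector of feature names.
#' @export
importance_subset <- function(train_pool, valid_pool, n_top = 50L,
                              classifier = classifier_spec(), seed = 1L) {
  if (nrow(train_pool) == 0 || nrow(valid_pool) == 0) {
    abort("both pools must be nonempty")
  }
  feats <- intersect(feature_names(train_pool), feature_names(valid_pool))
  locs <- union(unique(train_pool$location), unique(valid_pool$location))
  top_for <- function(tr, va) {
    x <- bind_rows(tr[, feats, drop = FALSE], va[, feats, drop = FALSE])
    y <- factor(c(rep(0L, nrow(tr)), rep(1L, nrow(va))))
    rf <- ranger::ranger(x = as.data.frame(x), y = y,
                         num.trees = classifier$num_trees,
                         importance = "impurity", seed = seed,
                         num.threads = 1)
    imp <- sort(rf$variable.importance, decreasing = TRUE)
    names(head(imp, n_top))
  }
  if (length(locs) <= 1) {
    return(top_for(train_pool, valid_pool))
  }
  sets <- lapply(locs, function(l) {
    tr <- train_pool[train_pool$location == l, , drop = FALSE]
    va <- valid_pool[valid_pool$location == l, , drop = FALSE]
    if (nrow(tr) == 0 || nrow(va) == 0) return(character(0))
    top_for(tr, va)
  })
  Reduce(union, sets)
}
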