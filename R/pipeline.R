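#' Pipeline configuration
#'
#' @param classifier A [classifier_spec()] used by every learning stage.
#' @param ssl_general,ssl_vehicle [ssl_strategy()] objects for the general
#'   and vehicle self-training stages. Defaults for the chain-smoothing
#'   (2019-style) pipeline: confident-agreement selection with
#'   classifier labels (`S2`, thr 0.5, CLF), the most reliable HMM-aware
#'   strategy under the synthetic study conditions; the HMM-free (2020-style) pipeline overrides these
#'   with confidence-only `S1` selection.
#' @param pseudocount Additive smoothing for all HMM estimates.
#' @param r_threshold Correlation-pruning threshold for feature selection.
#' @param feature_selection Whether the 2020-style pipeline runs
#'   quarter-fold feature selection for its general classifier.
#' @param max_candidates Wrapper candidate cap for feature selection.
#' @param seed Master seed; all stage seeds derive from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(classifier = classifier_spec(),
                            ssl_general = ssl_strategy("S2", 0.5, "CLF"),
                            ssl_vehicle = ssl_strategy("S2", 0.5, "CLF"),
                            pseudocount = 0.1,
                            r_threshold = 0.9,
                            feature_selection = TRUE,
                            max_candidates = 25L,
                            seed = 1L) {
  structure(
    list(classifier = classifier, ssl_general = ssl_general,
         ssl_vehicle = ssl_vehicle, pseudocount = pseudocount,
         r_threshold = r_threshold, feature_selection = feature_selection,
         max_candidates = as.integer(max_candidates), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Contiguous four-fold cross-validation scheme
#'
#' Splits a validation-style table into four contiguous quarters (in row
#' order, preserving temporal contiguity); fold i tests quarter i and trains
#' on the remaining three quarters (plus whatever pool the caller adds).
#'
#' @param validation_set A feature table with at least 4 rows.
#' @return An object of class `cv_scheme`: list with `quarter` (per-row
#'   quarter id) and `folds` (list of `train`/`test` index vectors).
#' @export
make_cv_scheme <- function(validation_set) {
  n <- nrow(validation_set)
  if (is.null(n) || n < 4) abort("need at least 4 windows for quarter folds")
  quarter <- ceiling(seq_len(n) * 4 / n)
  quarter[quarter > 4] <- 4L
  folds <- lapply(1:4, function(q) {
    list(train = which(quarter != q), test = which(quarter == q))
  })
  structure(list(quarter = as.integer(quarter), folds = folds),
            class = "cv_scheme")
}

#' Split predictions into vehicle and non-vehicle masks
#'
#' @param preds Integer predicted labels.
#' @return A list of two complementary logical masks, `vehicle` (still, car,
#'   bus, train, subway — the stationary-body classes) and `non_vehicle`
#'   (walk, run, bike).
#' @export
split_vehicle <- function(preds) {
  check_labels(preds)
  vehicle <- preds %in% vehicle_codes()
  list(vehicle = vehicle, non_vehicle = !vehicle)
}

#' Merge vehicle-model reclassifications into general predictions
#'
#' @param general_preds Integer predictions for all instances.
#' @param vehicle_preds Vehicle-model predictions for the masked positions
#'   (must all be vehicle classes).
#' @param mask Logical vector marking the positions to replace.
#' @return The merged prediction vector.
#' @export
reclassify_vehicle <- function(general_preds, vehicle_preds, mask) {
  if (sum(mask) != length(vehicle_preds)) {
    abort("vehicle_preds length must equal number of masked positions")
  }
  if (any(!vehicle_preds %in% vehicle_codes())) {
    abort("vehicle model emitted a dynamic class")
  }
  out <- general_preds
  out[mask] <- vehicle_preds
  out
}

# Maximal runs of mask==TRUE within each ordered chain; returned as index
# vectors (into the full set) preserving chain order.
mask_runs <- function(chains, mask) {
  runs <- list()
  for (ch in chains) {
    keep <- mask[ch]
    if (!any(keep)) next
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      runs[[length(runs) + 1]] <- ch[starts[k]:ends[k]]
    }
  }
  runs
}

# Run the secondary (analogous-classifier) four-fold CV pipeline: execute
# `stage` once per fold, pool its held-quarter predictions, and fit the HMM
# from the pooled confusion matrix plus training-label transitions.
secondary_hmm <- function(train_pool, valid_set, features, stage,
                          train_label_sequences, pseudocount = 1) {
  scheme <- make_cv_scheme(valid_set)
  preds <- integer(nrow(valid_set))
  for (fold in scheme$folds) {
    labeled <- bind_rows(train_pool, valid_set[fold$train, , drop = FALSE])
    preds[fold$test] <- stage(labeled, valid_set[fold$test, , drop = FALSE])
  }
  params <- fit_secondary_hmm(preds, valid_set$label, train_label_sequences,
                              pseudocount)
  list(params = params, cv_predictions = preds)
}

new_pipeline_result <- function(stages, stage_predictions, truth, config,
                                extra = list()) {
  stage_f1 <- vapply(stage_predictions, function(p) {
    if (is.null(truth)) NA_real_ else macro_f1(confusion_matrix(truth, p))
  }, numeric(1))
  final <- stage_predictions[[length(stage_predictions)]]
  cm <- if (!is.null(truth)) confusion_matrix(truth, final) else NULL
  structure(
    c(list(
      stages = tibble::tibble(stage = stages, macro_f1 = stage_f1),
      stage_predictions = stats::setNames(stage_predictions, stages),
      predictions = final,
      confusion = cm,
      per_class_f1 = if (!is.null(cm)) per_class_f1(cm) else NULL,
      config = config, seed = config$seed
    ), extra),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$stages, n = nrow(x$stages))
  invisible(x)
}

#' Run the chain-smoothing (2019-style) hierarchical pipeline
#'
#' The full location-shift pipeline: a general classifier trained with
#' HMM-aware self-training and smoothed per ordered chain, followed by a
#' vehicle classifier (trained on vehicle-class instances only) that
#' reclassifies the windows the general stage called vehicle, itself
#' self-trained and smoothed. HMM parameters come from a secondary
#' four-fold cross-validation replica of each stage (the "analogous
#' classifier"), using contiguous validation quarters; transitions come from
#' the training label sequence. Five stage-wise prediction sets are
#' recorded: general classifier (GC), GC + HMM, self-trained GC + HMM, plus
#' vehicle reclassification without and with vehicle self-training.
#'
#' @param train,validation Labeled feature tables in temporal row order.
#' @param test Feature table to predict (its `label` column, if present, is
#'   never read except for final metrics via `test_labels`).
#' @param chains List of index vectors into `test` giving locally ordered
#'   chains (from [reorder_data()]); if `NULL` the HMM-free pipeline is run
#'   instead, with a warning.
#' @param config A [pipeline_config()].
#' @param test_labels Optional true labels of `test`, used only to compute
#'   stage metrics.
#' @return A `pipeline_result`; see [tidy.pipeline_result()].
#' @export
run_pipeline_2019 <- function(train, validation, test, chains,
                              config = pipeline_config(),
                              test_labels = NULL) {
  if (is.null(chains)) {
    warn("no ordered chains supplied; falling back to the HMM-free pipeline")
    return(run_pipeline_2020(train, validation, test, config, test_labels,
                             locate_first = FALSE))
  }
  clf <- config$classifier
  seed <- config$seed
  feats <- Reduce(intersect, list(feature_names(train),
                                  feature_names(validation),
                                  feature_names(test)))
  labeled <- bind_rows(train, validation)
  train_seq <- label_sequences(train)

  plain_stage <- function(labeled_ft, test_ft) {
    fit <- clf_fit(clf, labeled_ft[, feats, drop = FALSE], labeled_ft$label,
                   seed)
    clf_predict(fit, test_ft[, feats, drop = FALSE])$labels
  }

  # --- general classifier ---
  gc_hmm <- secondary_hmm(train, validation, feats, plain_stage, train_seq,
                          config$pseudocount)
  gc_fit <- clf_fit(clf, labeled[, feats, drop = FALSE], labeled$label, seed)
  preds_gc <- clf_predict(gc_fit, test[, feats, drop = FALSE])$labels
  preds_gc_hmm <- smooth_per_chain(preds_gc, chains, gc_hmm$params)

  # --- self-trained general classifier ---
  ssl_gc <- self_train(labeled, test, config$ssl_general, clf,
                       hmm = gc_hmm$params, chains = chains,
                       features = feats, seed = seed)
  ssl_stage <- function(labeled_ft, test_ft) {
    self_train(labeled_ft, test_ft, config$ssl_general, clf,
               hmm = gc_hmm$params, chains = list(seq_len(nrow(test_ft))),
               features = feats, seed = seed)$predictions
  }
  ssl_hmm <- secondary_hmm(train, validation, feats, ssl_stage, train_seq,
                           config$pseudocount)
  preds_ssl_hmm <- smooth_per_chain(ssl_gc$predictions, chains,
                                    ssl_hmm$params)

  # --- vehicle classifier on the instances called vehicle ---
  mask <- split_vehicle(preds_ssl_hmm)$vehicle
  veh_classes <- vehicle_codes()
  veh_train <- train[train$label %in% veh_classes, , drop = FALSE]
  veh_valid <- validation[validation$label %in% veh_classes, , drop = FALSE]
  veh_labeled <- bind_rows(veh_train, veh_valid)
  veh_seq <- unlist(lapply(train_seq, vehicle_label_runs), recursive = FALSE)
  stage_names <- c("GC", "GC + HMM", "SSL(GC,HMM) + HMM",
                   "SSL(GC,HMM) + HMM + VC + HMM",
                   "SSL(GC,HMM) + HMM + SSL(VC,HMM) + HMM")

  if (!any(mask) || nrow(veh_labeled) == 0 || nrow(veh_valid) < 4) {
    preds <- list(preds_gc, preds_gc_hmm, preds_ssl_hmm, preds_ssl_hmm,
                  preds_ssl_hmm)
    return(new_pipeline_result(stage_names, preds, test_labels, config,
                               list(chains = chains)))
  }

  test_veh <- test[mask, , drop = FALSE]
  veh_chain_runs <- mask_runs(chains, mask)
  veh_pos <- lapply(veh_chain_runs, function(ix) match(ix, which(mask)))

  vc_hmm <- secondary_hmm(veh_train, veh_valid, feats, plain_stage, veh_seq,
                          config$pseudocount)
  vc_fit <- clf_fit(clf, veh_labeled[, feats, drop = FALSE],
                    veh_labeled$label, seed)
  preds_vc <- clf_predict(vc_fit, test_veh[, feats, drop = FALSE])$labels
  preds_vc_hmm <- smooth_positions(preds_vc, veh_pos, vc_hmm$params)
  row4 <- reclassify_vehicle(preds_ssl_hmm, preds_vc_hmm, mask)

  ssl_vc <- self_train(veh_labeled, test_veh, config$ssl_vehicle, clf,
                       hmm = vc_hmm$params, chains = veh_pos,
                       features = feats, seed = seed)
  vc_ssl_stage <- function(labeled_ft, test_ft) {
    self_train(labeled_ft, test_ft, config$ssl_vehicle, clf,
               hmm = vc_hmm$params, chains = list(seq_len(nrow(test_ft))),
               features = feats, seed = seed)$predictions
  }
  vc_ssl_hmm <- secondary_hmm(veh_train, veh_valid, feats, vc_ssl_stage,
                              veh_seq, config$pseudocount)
  preds_vc_ssl_hmm <- smooth_positions(ssl_vc$predictions, veh_pos,
                                       vc_ssl_hmm$params)
  row5 <- reclassify_vehicle(preds_ssl_hmm, preds_vc_ssl_hmm, mask)

  new_pipeline_result(
    stage_names,
    list(preds_gc, preds_gc_hmm, preds_ssl_hmm, row4, row5),
    test_labels, config,
    list(chains = chains,
         general_hmm = gc_hmm$params, vehicle_hmm = vc_hmm$params,
         ssl_general = ssl_gc, ssl_vehicle = ssl_vc)
  )
}

smooth_per_chain <- function(preds, chains, params) {
  out <- preds
  for (ch in chains) out[ch] <- smooth_predictions(preds[ch], params)
  out
}

# Smooth predictions given position lists into the prediction vector.
smooth_positions <- function(preds, position_runs, params) {
  out <- preds
  for (pos in position_runs) out[pos] <- smooth_predictions(preds[pos], params)
  out
}

# Contiguous vehicle-class runs of a label sequence (for vehicle-HMM
# transition estimation: transitions are only counted inside such runs).
vehicle_label_runs <- function(labels) {
  mask <- labels %in% vehicle_codes()
  if (!any(mask)) return(list())
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in which(r$values)) {
    out[[length(out) + 1]] <- labels[starts[k]:ends[k]]
  }
  out
}

#' Run the HMM-free (2020-style) pipeline with location gating
#'
#' The person-shift pipeline: detect the test set's phone location from its
#' dynamic (walking/running) windows, keep the location-matching part of the
#' training pool, optionally adapt the general classifier's features by
#' quarter-fold selection, train the general classifier with confidence-only
#' self-training, then reclassify the vehicle-called windows with a
#' self-trained vehicle classifier using the full feature set. Four
#' stage-wise prediction sets are recorded: GC, SSL(GC), SSL(GC) + VC,
#' SSL(GC) + SSL(VC).
#'
#' @inheritParams run_pipeline_2019
#' @param locate_first Run the location-detection gate (needs `location`
#'   columns); when `FALSE`, or when the location is undecidable, all
#'   training locations are used (with a warning in the undecidable case).
#' @param ssl_threshold Threshold for the confidence-only (`S1`) selection
#'   used by both classifiers.
#' @return A `pipeline_result`.
#' @export
run_pipeline_2020 <- function(train, validation, test,
                              config = pipeline_config(),
                              test_labels = NULL, locate_first = TRUE,
                              ssl_threshold = 0.5) {
  clf <- config$classifier
  seed <- config$seed
  feats <- Reduce(intersect, list(feature_names(train),
                                  feature_names(validation),
                                  feature_names(test)))
  extra <- list()

  train_pool <- train
  if (locate_first) {
    dyn_model <- fit_dynamic_detector(validation, clf, seed)
    flags <- detect_dynamic(test, dyn_model)
    loc_train <- validation[validation$label %in% c(2L, 3L), , drop = FALSE]
    decision <- if (any(flags) && nrow(loc_train) > 0 &&
                    length(unique(loc_train$location)) > 1) {
      loc_model <- fit_location_detector(loc_train, clf, seed)
      detect_location(test, flags, loc_model)
    } else {
      structure(list(per_window = NULL, counts = integer(0),
                     aggregate = NA_character_, n_dynamic = sum(flags)),
                class = "location_decision")
    }
    extra$location_decision <- decision
    if (!is.na(decision$aggregate) &&
        any(train$location == decision$aggregate)) {
      train_pool <- train[train$location == decision$aggregate, , drop = FALSE]
    } else if (is.na(decision$aggregate)) {
      warn("phone location undecidable; using all training locations")
    }
  }
  labeled <- bind_rows(train_pool, validation)

  gc_feats <- feats
  if (isTRUE(config$feature_selection)) {
    sel <- adapt_across_quarters(
      train_pool[, c("label", feats), drop = FALSE],
      validation[, c("label", feats), drop = FALSE],
      scheme = "intersection", r_threshold = config$r_threshold,
      classifier = clf, seed = seed, max_candidates = config$max_candidates
    )
    if (length(sel) > 0) gc_feats <- as.character(sel)
    extra$selected_features <- gc_feats
  }

  strategy <- ssl_strategy("S1", ssl_threshold, "CLF")
  gc_fit <- clf_fit(clf, labeled[, gc_feats, drop = FALSE], labeled$label,
                    seed)
  preds_gc <- clf_predict(gc_fit, test[, gc_feats, drop = FALSE])$labels
  ssl_gc <- self_train(labeled, test, strategy, clf, features = gc_feats,
                       seed = seed)
  preds_ssl <- ssl_gc$predictions

  mask <- split_vehicle(preds_ssl)$vehicle
  stage_names <- c("GC", "SSL(GC)", "SSL(GC) + VC", "SSL(GC) + SSL(VC)")
  if (!any(mask)) {
    preds <- list(preds_gc, preds_ssl, preds_ssl, preds_ssl)
    return(new_pipeline_result(stage_names, preds, test_labels, config,
                               extra))
  }
  veh_labeled <- labeled[labeled$label %in% vehicle_codes(), , drop = FALSE]
  test_veh <- test[mask, , drop = FALSE]
  vc_fit <- clf_fit(clf, veh_labeled[, feats, drop = FALSE],
                    veh_labeled$label, seed)
  preds_vc <- clf_predict(vc_fit, test_veh[, feats, drop = FALSE])$labels
  row3 <- reclassify_vehicle(preds_ssl, preds_vc, mask)
  ssl_vc <- self_train(veh_labeled, test_veh, strategy, clf,
                       features = feats, seed = seed)
  row4 <- reclassify_vehicle(preds_ssl, ssl_vc$predictions, mask)

  new_pipeline_result(
    stage_names, list(preds_gc, preds_ssl, row3, row4), test_labels, config,
    c(extra, list(ssl_general = ssl_gc, ssl_vehicle = ssl_vc))
  )
}
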