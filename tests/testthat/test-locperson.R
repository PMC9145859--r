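test_that("the location aggregator follows plurality", {
  expect_equal(aggregate_location(table4_counts()), "hips")
  expect_equal(aggregate_location(c(bag = 10, hand = 0, hips = 0, torso = 0)),
               "bag")
  expect_true(is.na(aggregate_location(integer(0))))
})

test_that("dynamic windows are detected from activity structure", {
  mix <- c(0.4, 0.3, 0.3, 0, 0, 0, 0, 0)
  train <- featurize_session(generate_session(
    session_config(seed = 21, duration = 500, mean_dwell = 25,
                   class_mix = mix), domain_spec("hips")))
  test <- featurize_session(generate_session(
    session_config(seed = 22, duration = 300, mean_dwell = 25,
                   class_mix = mix), domain_spec("hips")))
  model <- fit_dynamic_detector(train, fast_classifier())
  flags <- detect_dynamic(test, model)
  truth <- test$label %in% c(2L, 3L)
  expect_gte(mean(flags == truth), 0.95)
  # still-only windows are almost never flagged dynamic
  still <- featurize_session(generate_session(
    session_config(seed = 23, duration = 200,
                   class_mix = c(1, rep(0, 7))), domain_spec("hips")))
  expect_gte(mean(!detect_dynamic(still, model)), 0.98)
  expect_error(detect_dynamic(test, "not a model"), "fitted_classifier")
})

test_that("phone location is recovered from walking windows across seeds", {
  mix <- c(0, 0.6, 0.4, 0, 0, 0, 0, 0)
  locs <- c("bag", "hand", "hips", "torso")
  hits <- 0
  for (s in 1:5) {
    train <- dplyr::bind_rows(lapply(locs, function(l) {
      featurize_session(generate_session(
        session_config(seed = 100 * s + match(l, locs), duration = 200,
                       mean_dwell = 20, class_mix = mix),
        domain_spec(l)))
    }))
    target <- locs[(s %% 4) + 1]
    test <- featurize_session(generate_session(
      session_config(seed = 100 * s + 9, duration = 150, mean_dwell = 20,
                     class_mix = mix), domain_spec(target)))
    model <- fit_location_detector(train, fast_classifier())
    decision <- detect_location(test, rep(TRUE, nrow(test)), model)
    hits <- hits + (decision$aggregate == target)
  }
  expect_gte(hits, 4)
})

test_that("zero dynamic windows yield an undecidable location, not a crash", {
  d <- tibble::tibble(window_id = 1:3, order_key = 1:3, label = 1L,
                      location = "hips", user = 1L, f1 = stats::rnorm(3))
  decision <- detect_location(d, rep(FALSE, 3), model = NULL)
  expect_true(is.na(decision$aggregate))
  expect_equal(decision$n_dynamic, 0)
})

test_that("two separated blobs cluster perfectly with a high silhouette", {
  set.seed(4)
  n <- 60
  ft <- tibble::tibble(
    window_id = 1:n, order_key = 1:n, label = 1L, location = "hips",
    user = rep(1:2, each = n / 2),
    f1 = c(stats::rnorm(n / 2), stats::rnorm(n / 2, mean = 8)),
    f2 = c(stats::rnorm(n / 2), stats::rnorm(n / 2, mean = -8))
  )
  ca <- cluster_persons(ft, seed = 1)
  expect_gt(ca$silhouette, 0.5)
  expect_equal(length(unique(ca$assignment$cluster[ft$user == 1])), 1)
  expect_equal(length(unique(ca$assignment$cluster[ft$user == 2])), 1)
  # identical points cannot be clustered
  flat <- dplyr::mutate(ft, f1 = 1, f2 = 1)
  expect_error(cluster_persons(flat, seed = 1), "distinct")
})

test_that("chain smoothing reassigns windows to the chain majority", {
  set.seed(9)
  n <- 20
  ft <- tibble::tibble(
    window_id = 1:n, order_key = 1:n, label = 1L, location = "hips",
    user = 1L,
    f1 = c(stats::rnorm(12, 0), stats::rnorm(8, 6))
  )
  # one chain holding rows 1-10 split 6/4 between the clusters
  ft$f1[7:10] <- stats::rnorm(4, 6)
  ca <- cluster_persons(ft, chains = list(1:10, 11:20), seed = 1)
  expect_equal(length(unique(ca$assignment$smoothed[1:10])), 1)
  maj <- as.integer(names(which.max(table(ca$assignment$cluster[1:10]))))
  expect_equal(unique(ca$assignment$smoothed[1:10]), maj)
})

test_that("pool-separating features surface domain-encoding columns", {
  set.seed(11)
  n <- 80
  make_pool <- function(shifted) {
    tibble::tibble(
      window_id = 1:n, order_key = 1:n, label = 1L, location = "hips",
      user = 1L,
      gait = stats::rnorm(n, mean = if (shifted) 3 else 0),
      other1 = stats::rnorm(n), other2 = stats::rnorm(n)
    )
  }
  sel <- importance_subset(make_pool(FALSE), make_pool(TRUE), n_top = 1,
                           classifier = fast_classifier())
  expect_identical(sel, "gait")
  all_sel <- importance_subset(make_pool(FALSE), make_pool(TRUE), n_top = 99)
  expect_setequal(all_sel, c("gait", "other1", "other2"))
  expect_error(importance_subset(make_pool(FALSE)[0, ], make_pool(TRUE)),
               "nonempty")
})

test_that("cluster structure reflects users rather than activities", {
  # two users with distinct gaits recorded over two activities: clustering
  # within each activity subset matches the all-data clustering
  mix <- c(0.5, 0.5, 0, 0, 0, 0, 0, 0)
  fu <- lapply(1:2, function(u) {
    featurize_session(generate_session(
      session_config(seed = 30 + u, duration = 400, mean_dwell = 25,
                     class_mix = mix),
      domain_spec("hips", user = u,
                  user_gait_freq = c(1.5, 2.2)[u],
                  user_gait_amp = c(2, 3.2)[u])))
  })
  ft <- dplyr::bind_rows(fu)
  # cluster on user-discriminative features, as the method prescribes
  subset <- importance_subset(fu[[1]], fu[[2]], n_top = 30,
                              classifier = fast_classifier())
  walk_rows <- which(ft$label == 2L)
  global <- cluster_persons(ft, features = subset,
                            seed = 1)$assignment$cluster
  walk_only <- cluster_persons(ft[walk_rows, ], features = subset,
                               seed = 1)$assignment$cluster
  agree <- mean(walk_only == global[walk_rows])
  expect_gte(max(agree, 1 - agree), 0.8)
})
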