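make_feature_table <- function(n = 300, seed = 1) {
  set.seed(seed)
  label <- sample(1:4, n, replace = TRUE)
  tibble::tibble(
    window_id = seq_len(n), order_key = seq_len(n),
    label = as.integer(label), location = "hips", user = 1L,
    f_label_copy = as.numeric(label),
    f_informative = label + stats::rnorm(n, sd = 0.4),
    f_noise1 = stats::rnorm(n),
    f_noise2 = stats::rnorm(n),
    f_dup = as.numeric(label)
  )
}

test_that("a label copy is ranked first with MI equal to the label entropy", {
  ft <- make_feature_table()
  ranked <- rank_mutual_information(ft)
  expect_equal(ranked$feature[1], "f_dup") # ties broken by name
  expect_equal(ranked$feature[2], "f_label_copy")
  expect_equal(unname(ranked$mi[1]), label_entropy(ft$label),
               tolerance = 1e-9)
  expect_equal(unname(ranked$mi[1]), unname(ranked$mi[2]))
  expect_true(all(diff(ranked$mi) <= 1e-12))
  expect_true(all(ranked$mi >= 0))
  expect_error(
    rank_mutual_information(dplyr::mutate(ft, label = 1L)), "2 classes")
})

test_that("an independently shuffled feature has MI inside the null band", {
  ft <- make_feature_table(n = 200, seed = 3)
  set.seed(9)
  ft$f_shuffled <- sample(ft$f_informative)
  observed <- rank_mutual_information(ft)
  mi_obs <- observed$mi[observed$feature == "f_shuffled"]
  null <- replicate(1000, {
    perm <- ft
    perm$label <- sample(perm$label)
    r <- rank_mutual_information(perm[, c("window_id", "order_key", "label",
                                          "location", "user", "f_shuffled")])
    r$mi[1]
  })
  expect_lt(mi_obs, stats::quantile(null, 0.975))
})

test_that("correlation pruning keeps the higher-MI member of each pair", {
  ft <- make_feature_table()
  ranked <- rank_mutual_information(ft)
  kept <- prune_correlated(ranked, ft, r_threshold = 0.9)
  # exact duplicate: only the earlier-ranked copy survives
  expect_true("f_dup" %in% kept)
  expect_false("f_label_copy" %in% kept)
  cors <- abs(stats::cor(as.matrix(ft[, as.character(kept)])))
  diag(cors) <- 0
  expect_lte(max(cors), 0.9)
  # threshold 1 with uncorrelated features changes nothing
  sub <- ft[, c("window_id", "order_key", "label", "location", "user",
                "f_noise1", "f_noise2")]
  r2 <- rank_mutual_information(sub)
  expect_setequal(as.character(prune_correlated(r2, sub, 0.9)),
                  c("f_noise1", "f_noise2"))
  expect_error(prune_correlated(ranked, ft, 0), "in \\(0, 1\\]")
})

test_that("pruning matches an exhaustive pairwise check on random features", {
  set.seed(21)
  n <- 120
  base <- stats::rnorm(n)
  ft <- tibble::tibble(
    window_id = 1:n, order_key = 1:n,
    label = rep(1:2, length.out = n), location = "x", user = 1L
  )
  for (j in 1:10) {
    ft[[paste0("v", j)]] <- if (j %% 3 == 0) {
      base + stats::rnorm(n, sd = 0.3)
    } else {
      stats::rnorm(n)
    }
  }
  ranked <- rank_mutual_information(ft)
  kept <- as.character(prune_correlated(ranked, ft, r_threshold = 0.5))
  # oracle: walk the ranking, keep a feature iff |r| <= 0.5 with all kept
  cors <- abs(stats::cor(as.matrix(ft[, ranked$feature])))
  oracle <- character(0)
  for (f in ranked$feature) {
    if (length(oracle) == 0 || all(cors[f, oracle] <= 0.5)) {
      oracle <- c(oracle, f)
    }
  }
  expect_identical(kept, oracle)
})

test_that("the greedy wrapper keeps only strict improvements", {
  ft <- make_feature_table(n = 400, seed = 5)
  train <- ft[1:200, ]
  valid <- ft[201:400, ]
  # a perfect first feature cannot be improved upon
  res <- greedy_wrapper(train, valid,
                        c("f_label_copy", "f_noise1", "f_noise2"),
                        classifier = centroid_classifier())
  expect_identical(res$selected, "f_label_copy")
  expect_equal(res$audit$accuracy[1], 1)
  expect_true(res$audit$kept[1])
  expect_false(any(res$audit$kept[-1]))
  # single candidate: selected with one audit entry
  res1 <- greedy_wrapper(train, valid, "f_noise1",
                         classifier = centroid_classifier())
  expect_identical(res1$selected, "f_noise1")
  expect_equal(nrow(res1$audit), 1)
  expect_error(greedy_wrapper(train, valid, character(0)), "no candidate")
  # wrapper monotonicity: accuracy at accepted steps strictly increases
  res2 <- greedy_wrapper(train, valid,
                         c("f_noise1", "f_informative", "f_label_copy"),
                         classifier = centroid_classifier())
  acc_kept <- res2$audit$accuracy[res2$audit$kept]
  expect_true(all(diff(acc_kept) > 0))
})

test_that("the wrapper recovers informative features and rejects noise", {
  set.seed(17)
  recalls <- c()
  noise_rates <- c()
  for (rep in 1:15) {
    n <- 300
    y <- sample(1:3, n, replace = TRUE)
    ft <- tibble::tibble(window_id = 1:n, order_key = 1:n,
                         label = as.integer(y), location = "x", user = 1L)
    informative <- paste0("inf", 1:3)
    for (f in informative) ft[[f]] <- y + stats::rnorm(n, sd = 0.8)
    noise <- paste0("noise", 1:10)
    for (f in noise) ft[[f]] <- stats::rnorm(n)
    train <- ft[1:150, ]
    valid <- ft[151:300, ]
    sel <- select_features(train, valid, classifier = centroid_classifier(),
                           seed = rep)$selected
    recalls <- c(recalls, mean(informative %in% sel))
    noise_rates <- c(noise_rates, mean(noise %in% sel))
  }
  expect_gte(mean(recalls), 0.9)
  expect_lte(mean(noise_rates), 0.2)
})

test_that("quarter-fold adaptation intersects or unions per-fold choices", {
  ft <- make_feature_table(n = 240, seed = 8)
  sel <- adapt_across_quarters(ft[1:40, ], ft[41:240, ],
                               classifier = centroid_classifier())
  expect_true(length(sel) >= 1)
  folds <- attr(sel, "folds")
  expect_length(folds, 4)
  expect_setequal(as.character(sel), Reduce(intersect, folds))
  # union scheme on the same folds is a superset
  sel_u <- adapt_across_quarters(ft[1:40, ], ft[41:240, ], scheme = "union",
                                 classifier = centroid_classifier())
  expect_true(all(as.character(sel) %in% as.character(sel_u)))
  expect_error(adapt_across_quarters(ft[1:40, ], ft[1:2, ]), "4 quarters")
})
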