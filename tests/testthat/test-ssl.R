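test_that("selection predicates follow their definitions exactly", {
  probs <- c(0.95, 0.8, 0.6, 0.4, 0.2)
  clf <- c(1L, 2L, 3L, 1L, 2L)
  hmm <- c(1L, 3L, 3L, 2L, 2L)
  # strict threshold: thr = 1 selects nothing under S1
  expect_length(select_instances(probs, clf,
                                 strategy = ssl_strategy("S1", 1.0))$index, 0)
  s1 <- select_instances(probs, clf, hmm, ssl_strategy("S1", 0.5))
  expect_equal(s1$index, c(1, 2, 3))
  expect_equal(s1$labels, clf[1:3])
  s2 <- select_instances(probs, clf, hmm, ssl_strategy("S2", 0.5))
  expect_equal(s2$index, c(1, 3))
  s4 <- select_instances(probs, clf, hmm, ssl_strategy("S4", 0.5, "HMM"))
  expect_equal(s4$index, 4)
  expect_equal(s4$labels, hmm[4])
  expect_error(select_instances(probs, clf, strategy = ssl_strategy("S2")),
               "requires hmm_labels")
})

test_that("S5 is the disjoint union of S2 and S4", {
  set.seed(14)
  for (rep in 1:30) {
    n <- sample(5:20, 1)
    probs <- stats::runif(n)
    clf <- sample.int(4, n, replace = TRUE)
    hmm <- sample.int(4, n, replace = TRUE)
    thr <- sample(seq(0.1, 0.9, 0.2), 1)
    i2 <- select_instances(probs, clf, hmm, ssl_strategy("S2", thr))$index
    i4 <- select_instances(probs, clf, hmm, ssl_strategy("S4", thr))$index
    i5 <- select_instances(probs, clf, hmm, ssl_strategy("S5", thr))$index
    expect_setequal(i5, union(i2, i4))
    expect_length(intersect(i2, i4), 0)
  }
})

test_that("all predicates match brute-force evaluation on random instances", {
  set.seed(27)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    probs <- stats::runif(n)
    clf <- sample.int(3, n, replace = TRUE)
    hmm <- sample.int(3, n, replace = TRUE)
    for (pred in c("S1", "S2", "S3", "S4", "S5")) {
      for (thr in seq(0.1, 0.9, 0.2)) {
        got <- select_instances(probs, clf, hmm,
                                ssl_strategy(pred, thr))$index
        agree <- clf == hmm
        want <- which(switch(
          pred,
          S1 = probs > thr,
          S2 = probs > thr & agree,
          S3 = probs > thr & !agree,
          S4 = probs < thr & !agree,
          S5 = (probs > thr & agree) | (probs < thr & !agree)
        ))
        expect_equal(got, want)
      }
    }
  }
})

make_ssl_tables <- function(seed = 1, n = 120) {
  set.seed(seed)
  y <- sample(1:3, n, replace = TRUE)
  ft <- tibble::tibble(
    window_id = seq_len(n), order_key = seq_len(n), label = as.integer(y),
    location = "hips", user = 1L,
    f1 = y + stats::rnorm(n, sd = 0.5),
    f2 = -y + stats::rnorm(n, sd = 0.5),
    f3 = stats::rnorm(n)
  )
  list(labeled = ft[1:60, ], unlabeled = ft[61:n, ])
}

test_that("thr = 1 self-training is the identity on the model", {
  d <- make_ssl_tables()
  res <- self_train(d$labeled, d$unlabeled, ssl_strategy("S1", 1.0),
                    classifier = fast_classifier(), seed = 1)
  base <- clf_fit(fast_classifier(), d$labeled[, c("f1", "f2", "f3")],
                  d$labeled$label, 1)
  expect_identical(res$predictions,
                   clf_predict(base, d$unlabeled[, c("f1", "f2", "f3")])$labels)
  expect_equal(res$n_selected, 0)
  expect_true("no_selection_round_1" %in% res$warnings)
})

test_that("an unlabeled copy of the labeled set is fully selected at thr 0", {
  d <- make_ssl_tables()
  res <- self_train(d$labeled, d$labeled, ssl_strategy("S1", 0.0),
                    classifier = fast_classifier(), seed = 1)
  expect_equal(res$n_selected, nrow(d$labeled))
})

test_that("selected instances never alter the original labeled pool", {
  d <- make_ssl_tables(seed = 2)
  before <- d$labeled
  res <- self_train(d$labeled, d$unlabeled, ssl_strategy("S1", 0.3),
                    classifier = fast_classifier(), seed = 1)
  expect_identical(d$labeled, before)
  expect_lte(res$n_selected, nrow(d$unlabeled))
  expect_true(all(res$selected$n >= 0))
})

test_that("a one-class selection trips the degeneracy guard", {
  set.seed(5)
  n <- 80
  labeled <- tibble::tibble(
    window_id = 1:n, order_key = 1:n,
    label = rep(c(1L, 2L), each = n / 2), location = "x", user = 1L,
    f1 = rep(c(0, 5), each = n / 2) + stats::rnorm(n, sd = 0.1)
  )
  unlabeled <- tibble::tibble(
    window_id = 1:20, order_key = 1:20, label = 1L, location = "x",
    user = 1L, f1 = stats::rnorm(20, mean = 5, sd = 0.1)
  )
  res <- self_train(labeled, unlabeled, ssl_strategy("S1", 0.6),
                    classifier = fast_classifier(), seed = 1)
  expect_true(any(grepl("degenerate_selection", res$warnings)))
})

test_that("the strategy sweep reports the full grid shape", {
  d <- make_ssl_tables(seed = 3)
  sweep <- sweep_ssl_strategies(
    d$labeled, d$unlabeled, truth = d$unlabeled$label,
    classifier = fast_classifier(),
    thresholds = c(0.3, 0.7), predicates = "S1", label_sources = "CLF"
  )
  expect_equal(nrow(sweep), 2)
  expect_true(all(sweep$macro_f1 >= 0 & sweep$macro_f1 <= 1))
  expect_named(sweep,
               c("predicate", "label_source", "thr", "macro_f1", "n_selected"))
})
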