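test_that("transition estimation reproduces count arithmetic", {
  tr <- estimate_transitions(list(c(1L, 1L, 1L, 2L, 2L, 2L)),
                             pseudocount = 0, n_classes = 2)
  expect_equal(tr$transition[1, ], c(2 / 3, 1 / 3))
  expect_equal(tr$transition[2, ], c(0, 1))
  expect_equal(tr$initial, c(0.5, 0.5))
  # no cross-sequence transitions
  tr2 <- estimate_transitions(list(c(1L, 1L), c(2L, 2L)), 0, 2)
  expect_equal(tr2$transition, diag(2))
  # Laplace smoothing keeps rows stochastic and strictly positive
  tr3 <- estimate_transitions(list(c(1L, 2L, 1L)), pseudocount = 1,
                              n_classes = 3)
  expect_true(all(tr3$transition > 0))
  expect_equal(rowSums(tr3$transition), rep(1, 3))
  expect_error(estimate_transitions(list()), "no label sequences")
})

test_that("transition estimation recovers a known sticky matrix", {
  set.seed(12)
  K <- 4
  true_T <- matrix(0.02, K, K)
  diag(true_T) <- 0.94
  s <- integer(1e5)
  s[1] <- 1L
  for (t in 2:1e5) s[t] <- sample.int(K, 1, prob = true_T[s[t - 1], ])
  est <- estimate_transitions(list(s), pseudocount = 0, n_classes = K)
  expect_lt(max(abs(est$transition - true_T)), 0.02)
})

test_that("emissions come from row-normalised confusion counts", {
  expect_equal(emissions_from_confusion(diag(c(5, 9, 2)), 0), diag(3))
  cm <- matrix(c(20391, 2729, 2532, 92233), 2, byrow = TRUE)
  em <- emissions_from_confusion(cm, 0)
  expect_equal(em[1, ], c(0.8820, 0.1180), tolerance = 1e-4)
  expect_equal(emissions_from_confusion(matrix(3, 4, 4), 0),
               matrix(0.25, 4, 4))
  expect_error(emissions_from_confusion(rbind(c(1, 0), c(0, 0)), 0),
               "pseudocount")
})

test_that("hmm_params validates stochasticity", {
  expect_error(hmm_params(c(0.6, 0.6), diag(2), diag(2)), "probability")
  expect_error(hmm_params(c(0.5, 0.5), matrix(1, 2, 2), diag(2)),
               "transition")
  p <- hmm_params(c(0.5, 0.5), diag(2), diag(2))
  expect_s3_class(p, "hmm_params")
})

test_that("identity emissions make smoothing a no-op", {
  K <- 4
  trans <- matrix(0.02, K, K)
  diag(trans) <- 0.94
  p <- hmm_params(rep(1 / K, K), trans, diag(K))
  set.seed(3)
  obs <- sample.int(K, 50, replace = TRUE)
  expect_identical(smooth_predictions(obs, p), obs)
})

test_that("an isolated misclassification inside a run is corrected", {
  cm <- matrix(c(20391, 2729, 2532, 92233), 2, byrow = TRUE)
  em <- emissions_from_confusion(cm, 0)
  trans <- matrix(c(0.99, 0.01, 0.01, 0.99), 2)
  p <- hmm_params(c(0.5, 0.5), trans, em)
  obs <- c(rep(1L, 20), 2L, rep(1L, 20))
  expect_equal(smooth_predictions(obs, p), rep(1L, 41))
  # length-1 sequence: argmax over initial x emission column
  p1 <- hmm_params(c(0.9, 0.1), trans, matrix(c(0.6, 0.5, 0.4, 0.5), 2))
  expect_equal(smooth_predictions(2L, p1),
               which.max(p1$initial * p1$emission[, 2]))
})

test_that("zero-emission observations are rejected with advice", {
  em <- matrix(c(1, 1, 0, 0), 2)
  p <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2), em)
  expect_error(smooth_predictions(c(1L, 2L), p), "pseudocount")
})

test_that("smoothing is equivariant under class relabeling", {
  set.seed(6)
  p <- random_hmm(3)
  obs <- sample.int(3, 30, replace = TRUE)
  out <- smooth_predictions(obs, p)
  perm <- c(3L, 1L, 2L) # class i renamed perm[i]
  inv <- order(perm)
  p2 <- hmm_params(p$initial[inv], p$transition[inv, inv],
                   p$emission[inv, inv], 0)
  out2 <- smooth_predictions(perm[obs], p2)
  expect_identical(out2, perm[out])
})

test_that("posterior decoding agrees with Viterbi on easy sequences", {
  trans <- matrix(c(0.95, 0.05, 0.05, 0.95), 2)
  em <- matrix(c(0.9, 0.2, 0.1, 0.8), 2)
  p <- hmm_params(c(0.5, 0.5), trans, em)
  obs <- c(rep(1L, 15), rep(2L, 15))
  expect_equal(smooth_predictions(obs, p, method = "posterior"),
               smooth_predictions(obs, p))
})

test_that("the secondary-pipeline fit combines CV confusion and train labels", {
  set.seed(4)
  truth <- rep(1:3, each = 30)
  # perfect CV predictions: identity emissions up to smoothing
  p <- fit_secondary_hmm(truth, truth, list(rep(1:3, each = 10)),
                         pseudocount = 0, n_classes = 3)
  expect_equal(unname(p$emission), diag(3))
  expect_equal(unname(rowSums(p$transition)), rep(1, 3))
  expect_equal(unname(rowSums(p$emission)), rep(1, 3))
  expect_equal(sum(p$initial), 1)
  # label-shuffled CV predictions give near-uniform emission rows over the
  # observed class proportions
  shuffled <- sample(truth)
  p2 <- fit_secondary_hmm(shuffled, truth, list(rep(1:3, each = 10)),
                          pseudocount = 0, n_classes = 3)
  expect_lt(max(abs(p2$emission[1:3, 1:3] - 1 / 3)), 0.2)
  expect_error(
    fit_secondary_hmm(c(1L, 1L), c(1L, 1L), list(c(1L, 2L)), 0, 2),
    "absent"
  )
})

test_that("Viterbi smoothing recovers accuracy on noisy sticky chains", {
  set.seed(99)
  gains <- replicate(25, {
    truth <- sticky_sequence(800, k = 8, self_prob = 0.99)
    obs <- corrupt_labels(truth, rate = 0.2)
    trans <- matrix(0.01 / 7, 8, 8)
    diag(trans) <- 0.99
    em <- matrix(0.2 / 7, 8, 8)
    diag(em) <- 0.8
    p <- hmm_params(rep(1 / 8, 8), trans, em)
    sm <- smooth_predictions(obs, p)
    mean(sm == truth) - mean(obs == truth)
  })
  expect_gte(mean(gains), 0.08)
  expect_gte(mean(gains > 0), 0.95)
})
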