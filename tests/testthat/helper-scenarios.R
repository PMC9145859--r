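# Shared fixtures built in code. Scenario construction is the expensive part
# of the ML-level tests, so scenarios are memoised per (seed, kind) for the
# duration of the test run.

.scenario_cache <- new.env(parent = emptyenv())

# The canonical location-shift study conditions used by the directional
# checks: 4-class mix (still, walk, car, bus), sticky 25 s dwell, moderate
# sensor noise, car/bus separated near the per-window information limit.
location_scenario <- function(seed) {
  key <- paste0("loc_", seed)
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  sc <- make_shift_scenario(
    seed = seed, kind = "location",
    duration = 800, valid_duration = 700, mean_dwell = 25, noise_sd = 0.15,
    class_mix = c(0.25, 0.25, 0, 0, 0.25, 0.25, 0, 0)
  )
  .scenario_cache[[key]] <- sc
  sc
}

# A small, fully separable two-class scenario for structural / ceiling tests.
small_scenario <- function(seed = 2) {
  key <- paste0("small_", seed)
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  sc <- make_shift_scenario(
    seed = seed, kind = "location",
    duration = 300, valid_duration = 300, mean_dwell = 25, noise_sd = 0,
    class_mix = c(0.5, 0.5, 0, 0, 0, 0, 0, 0), bump_rate = 0
  )
  .scenario_cache[[key]] <- sc
  sc
}

fast_classifier <- function(num_trees = 64L) classifier_spec(num_trees)

# A deterministic nearest-centroid classifier behind the pluggable
# interface: cheap enough for wrapper Monte-Carlo tests.
centroid_classifier <- function() {
  classifier_spec(
    fit = function(x, y, seed) {
      x <- as.matrix(x)
      levels <- sort(unique(y))
      centers <- do.call(rbind, lapply(levels, function(l) {
        colMeans(x[y == l, , drop = FALSE])
      }))
      list(centers = centers, levels = levels)
    },
    predict_prob = function(model, x) {
      x <- as.matrix(x)
      d2 <- vapply(seq_len(nrow(model$centers)), function(k) {
        rowSums(sweep(x, 2, model$centers[k, ])^2)
      }, numeric(nrow(x)))
      d2 <- matrix(d2, nrow = nrow(x))
      w <- exp(-d2 / (2 * stats::median(d2)))
      w / rowSums(w)
    }
  )
}

# Random sticky label sequence with the given self-transition probability.
sticky_sequence <- function(n, k = 8L, self_prob = 0.99) {
  s <- integer(n)
  s[1] <- sample.int(k, 1)
  for (t in 2:n) {
    s[t] <- if (runif(1) < self_prob) s[t - 1] else
      sample(setdiff(seq_len(k), s[t - 1]), 1)
  }
  s
}

# Symmetric label noise: each position replaced by a uniform other class
# with probability `rate`.
corrupt_labels <- function(s, k = 8L, rate = 0.2) {
  flip <- runif(length(s)) < rate
  s[flip] <- vapply(s[flip], function(v) sample(setdiff(seq_len(k), v), 1),
                    integer(1))
  s
}

table2_matrix <- function() {
  matrix(c(20391, 2729, 2532, 92233), nrow = 2, byrow = TRUE,
         dimnames = list(true = c("walkrun", "other"),
                         predicted = c("walkrun", "other")))
}

table3_matrix <- function() {
  matrix(c(4050, 378, 558, 334,
           24, 5207, 19, 48,
           9, 1529, 5240, 280,
           222, 387, 218, 4420),
         nrow = 4, byrow = TRUE,
         dimnames = list(true = c("bag", "hand", "hips", "torso"),
                         predicted = c("bag", "hand", "hips", "torso")))
}

table4_counts <- function() c(bag = 95, hand = 2430, hips = 12901, torso = 38)

# Exhaustive maximum-probability path for tiny HMM instances (oracle for
# Viterbi): enumerates all K^n state paths and scores them directly.
brute_force_map_path <- function(obs, params) {
  K <- length(params$initial)
  n <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- log(params$initial[paths[, 1]]) +
    log(params$emission[cbind(paths[, 1], obs[1])])
  if (n > 1) {
    for (t in 2:n) {
      lp <- lp + log(params$transition[cbind(paths[, t - 1], paths[, t])]) +
        log(params$emission[cbind(paths[, t], obs[t])])
    }
  }
  as.integer(paths[which.max(lp), ])
}

random_hmm <- function(k) {
  rows <- function() {
    m <- matrix(stats::rgamma(k * k, 1) + 0.05, k)
    m / rowSums(m)
  }
  init <- stats::rgamma(k, 1) + 0.05
  hmm_params(init / sum(init), rows(), rows(), pseudocount = 0)
}
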