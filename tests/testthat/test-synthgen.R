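test_that("generation is reproducible and windows have the challenge shape", {
  cfg <- session_config(seed = 11, duration = 60)
  ws1 <- generate_session(cfg, domain_spec("bag"))
  ws2 <- generate_session(cfg, domain_spec("bag"))
  expect_identical(ws1, ws2)
  expect_length(ws1$windows, 12)
  expect_equal(dim(ws1$windows[[1]]), c(20, 500))
  expect_identical(rownames(ws1$windows[[1]]), channel_names())
  expect_identical(ws1$order_key, 1:12)
  expect_equal(dim(ws1$labels), c(12, 500))
})

test_that("a pure still session with zero noise is silent with gravity 9.81", {
  mix <- c(1, rep(0, 7))
  ws <- generate_session(
    session_config(seed = 3, duration = 30, noise_sd = 0, class_mix = mix),
    domain_spec("torso")
  )
  expect_true(all(ws$labels == 1L))
  acc <- do.call(cbind, lapply(ws$windows, function(w) w[1:3, ]))
  expect_equal(max(apply(acc, 1, stats::var)), 0)
  expect_equal(unname(magnitude(ws$windows[[1]][4:6, , drop = FALSE])),
               rep(9.81, 500), tolerance = 1e-9)
})

test_that("gravity norm and quaternion unit norm hold for every class mix", {
  ws <- generate_session(session_config(seed = 5, duration = 120),
                         domain_spec("hand"))
  for (w in ws$windows[c(1, 10, 24)]) {
    expect_equal(unname(magnitude(w[4:6, , drop = FALSE])), rep(9.81, 500),
                 tolerance = 1e-6)
    expect_equal(unname(sqrt(colSums(w[16:19, ]^2))), rep(1, 500),
                 tolerance = 1e-9)
  }
})

test_that("gait fundamental shows up at the configured frequency", {
  # oracle: dominant Welch bin of the vertical acceleration for walk-only
  # sessions at two gait frequencies differs by the configured 0.5 Hz
  mix <- c(0, 1, rep(0, 6))
  peak <- function(freq) {
    ws <- generate_session(
      session_config(seed = 9, duration = 100, noise_sd = 0.01,
                     class_mix = mix),
      domain_spec("hips", user_gait_freq = freq)
    )
    x <- unlist(lapply(ws$windows, function(w) w["LAcc_z", ]))
    w <- welch_psd(x, fs = 100, segment_sec = 4)
    w$freq[which.max(w$psd)]
  }
  p1 <- peak(1.6)
  p2 <- peak(2.1)
  expect_equal(p1, 1.6, tolerance = 0.15)
  expect_equal(p2, 2.1, tolerance = 0.15)
  expect_equal(p2 - p1, 0.5, tolerance = 0.3)
})

test_that("shuffling permutes uniformly and order_key undoes it", {
  ws <- generate_session(session_config(seed = 2, duration = 100),
                         domain_spec())
  sh <- shuffle_windows(ws, seed = 42)
  expect_identical(sort(sh$order_key), 1:20)
  expect_identical(sh$windows[order(sh$order_key)], ws$windows)
  expect_identical(sh$labels[order(sh$order_key), ], ws$labels)
  # single window: unchanged
  ws1 <- generate_session(session_config(seed = 2, duration = 5),
                          domain_spec())
  expect_identical(shuffle_windows(ws1, 7), ws1)
  # different seeds give different permutations on n = 20
  sh2 <- shuffle_windows(ws, seed = 43)
  expect_false(identical(sh$order_key, sh2$order_key))
})

test_that("window-level self-transition rate matches the dwell time", {
  ws <- generate_session(
    session_config(seed = 19, duration = 7200, mean_dwell = 60),
    domain_spec()
  )
  wl <- window_labels(ws)
  self_rate <- mean(wl[-1] == wl[-length(wl)])
  expect_equal(self_rate, 1 - 5 / 60, tolerance = 0.03)
})

test_that("location shift is attenuated for vehicle classes", {
  # the premise behind vehicle-specific models: across two phone locations,
  # vehicle windows are distributionally closer than walk windows
  cfg <- session_config(seed = 11, duration = 900, mean_dwell = 40,
                        class_mix = c(0, 0.5, 0, 0, 0.5, 0, 0, 0))
  fa <- featurize_session(generate_session(cfg, domain_spec("hips")))
  fb <- featurize_session(generate_session(cfg, domain_spec("hand")))
  smd <- function(lab) {
    a <- as.matrix(fa[fa$label == lab, feature_names(fa)])
    b <- as.matrix(fb[fb$label == lab, feature_names(fb)])
    s <- sqrt((apply(a, 2, stats::var) + apply(b, 2, stats::var)) / 2)
    mean(abs(colMeans(a) - colMeans(b)) / ifelse(s > 0, s, 1))
  }
  expect_gt(smd(2), smd(5))
})

test_that("invalid session configurations are rejected", {
  expect_error(session_config(duration = -5), "positive")
  expect_error(session_config(mean_dwell = 0), "positive")
  expect_error(session_config(duration = 7, window_len = 5), "multiple")
  expect_error(session_config(class_mix = rep(0.2, 8)), "summing to 1")
})

test_that("challenge text format round-trips", {
  ws <- generate_session(session_config(seed = 4, duration = 15),
                         domain_spec("bag", user = 2))
  dir <- withr::local_tempdir()
  write_challenge_format(ws, dir)
  expect_true(file.exists(file.path(dir, "Acc_x.txt")))
  expect_true(file.exists(file.path(dir, "Label.txt")))
  back <- read_challenge_format(dir)
  expect_identical(back$labels, ws$labels)
  expect_identical(back$order_key, ws$order_key)
  expect_equal(back$domain$location, "bag")
  for (i in seq_along(ws$windows)) {
    expect_equal(back$windows[[i]], ws$windows[[i]], tolerance = 1e-6)
  }
})

test_that("format errors name the offending file and row", {
  ws <- generate_session(session_config(seed = 4, duration = 15),
                         domain_spec())
  dir <- withr::local_tempdir()
  write_challenge_format(ws, dir)
  # truncate one row of the label file
  lines <- readLines(file.path(dir, "Label.txt"))
  lines[2] <- sub("^\\S+\\s", "", lines[2])
  writeLines(lines, file.path(dir, "Label.txt"))
  expect_error(read_challenge_format(dir), "Label.txt, row 2")
  # missing channel file
  file.remove(file.path(dir, "Gyr_y.txt"))
  expect_error(read_challenge_format(dir), "missing channel file: Gyr_y.txt")
  expect_error(read_challenge_format(withr::local_tempdir()),
               "session.json")
})
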