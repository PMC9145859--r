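#' Sensor channel layout of a challenge-style recording
#'
#' Twenty raw channels: triaxial acceleration, gravity, linear acceleration,
#' angular velocity (gyroscope), magnetic field, an orientation quaternion
#' (w, x, y, z) and barometric pressure, all sampled at a common rate.
#'
#' @return Character vector of the 20 canonical channel names.
#' @export
channel_names <- function() {
  c(
    paste0("Acc_", c("x", "y", "z")),
    paste0("Gra_", c("x", "y", "z")),
    paste0("LAcc_", c("x", "y", "z")),
    paste0("Gyr_", c("x", "y", "z")),
    paste0("Mag_", c("x", "y", "z")),
    paste0("Ori_", c("w", "x", "y", "z")),
    "Pressure"
  )
}

#' Describe a recording domain: phone location and wearer
#'
#' A domain couples an on-body phone location (bag, torso, hips, hand) with a
#' user identity. The location acts on the signals through a rigid rotation of
#' the triaxial channels plus a gain on the movement component; the user acts
#' through their gait fundamental frequency and amplitude. Location effects
#' are strong for dynamic activities (walk, run, bike), where limb placement
#' matters, and weak for vehicle activities, where every location feels much
#' the same vehicle vibration: when a sample carries a vehicle-class label the
#' rotation angle and gain excess are attenuated to a quarter of their value.
#'
#' @param location One of `"bag"`, `"torso"`, `"hips"`, `"hand"`.
#' @param user Integer user id (affects gait defaults).
#' @param location_gain Positive multiplier on movement amplitude. Default is
#'   location-specific (hips is the 1.0 reference).
#' @param rotation_angle Rotation angle in radians applied to triaxial
#'   channels; default location-specific.
#' @param rotation_axis Length-3 rotation axis (normalised internally).
#' @param user_gait_freq Walking-step fundamental in Hz (default 1.8 for
#'   user 1, 1.6 for user 2, 2.1 for user 3, 1.8 + 0.1 (u - 3) beyond).
#' @param user_gait_amp Gait acceleration amplitude scale in m/s^2.
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(location = c("hips", "bag", "torso", "hand"),
                        user = 1L,
                        location_gain = NULL,
                        rotation_angle = NULL,
                        rotation_axis = NULL,
                        user_gait_freq = NULL,
                        user_gait_amp = 2.5) {
  location <- match.arg(location)
  defaults <- list(
    hips  = list(gain = 1.0, angle = 0.0, axis = c(0, 0, 1)),
    bag   = list(gain = 1.3, angle = 0.9, axis = c(1, 0.3, 0.2)),
    torso = list(gain = 0.8, angle = 0.45, axis = c(0, 1, 0.3)),
    hand  = list(gain = 1.6, angle = 1.3, axis = c(0.2, 1, 1))
  )[[location]]
  gait_defaults <- c(1.8, 1.6, 2.1)
  user <- as.integer(user)
  if (is.null(user_gait_freq)) {
    user_gait_freq <- if (user <= 3) gait_defaults[max(user, 1L)] else 1.8 + 0.1 * (user - 3)
  }
  gain <- location_gain %||% defaults$gain
  if (gain <= 0) abort("location_gain must be > 0")
  structure(
    list(
      location = location,
      user = user,
      location_gain = gain,
      rotation_angle = rotation_angle %||% defaults$angle,
      rotation_axis = (rotation_axis %||% defaults$axis),
      user_gait_freq = user_gait_freq,
      user_gait_amp = user_gait_amp
    ),
    class = "domain_spec"
  )
}

#' Configure a synthetic recording session
#'
#' @param seed Integer RNG seed; two calls with the same config are
#'   bit-identical.
#' @param duration Session length in seconds; must be a positive multiple of
#'   `window_len`.
#' @param sample_rate Sampling rate in Hz (100, the challenge rate).
#' @param window_len Window length in seconds (5, the challenge segmentation).
#' @param mean_dwell Mean stay time per activity in seconds (semi-Markov
#'   exponential dwell); controls how sticky the label sequence is.
#' @param noise_sd Per-channel white measurement-noise standard deviation.
#' @param class_mix Probability vector over the 8 activity classes (sums
#'   to 1); next activities are drawn from it excluding the current one.
#' @param bump_rate Rate (events per second) of transient acceleration
#'   disturbances — road bumps, steps on kerbs, phone handling. Events are
#'   short damped oscillations added to the linear acceleration whenever
#'   the wearer is not stationary; they corrupt the affected window's
#'   features independently of its neighbours.
#' @param bump_amp Amplitude scale (m/s^2) of the transient disturbances.
#' @return An object of class `session_config`.
#' @export
session_config <- function(seed = 1L, duration = 600, sample_rate = 100,
                           window_len = 5, mean_dwell = 60, noise_sd = 0.05,
                           class_mix = rep(1 / 8, 8),
                           bump_rate = 0.12, bump_amp = 2.5) {
  if (duration <= 0) abort("duration must be positive")
  if (mean_dwell <= 0) abort("mean_dwell must be positive")
  if (abs(duration / window_len - round(duration / window_len)) > 1e-9) {
    abort("duration must be a multiple of window_len")
  }
  spw <- sample_rate * window_len
  if (abs(spw - round(spw)) > 1e-9) {
    abort("sample_rate * window_len must be an integer")
  }
  if (length(class_mix) != 8 || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-8) {
    abort("class_mix must be 8 nonnegative probabilities summing to 1")
  }
  structure(
    list(
      seed = as.integer(seed), duration = duration,
      sample_rate = sample_rate, window_len = window_len,
      mean_dwell = mean_dwell, noise_sd = noise_sd, class_mix = class_mix,
      bump_rate = bump_rate, bump_amp = bump_amp
    ),
    class = "session_config"
  )
}

# Vehicle-class vibration parameters: stationary sd (m/s^2) and AR(1)
# coefficient, giving each transportation mode a distinct variance and
# spectral tilt. `still` is pure measurement noise.
vehicle_signal_params <- function() {
  list(
    # car and bus share the vibration amplitude and differ only in spectral
    # tilt; train/subway are smoother (rail) with their own levels
    `1` = list(sd = 0,    phi = 0),      # still
    `5` = list(sd = 0.33, phi = 0.965),  # car
    `6` = list(sd = 0.40, phi = 0.945),  # bus
    `7` = list(sd = 0.30, phi = 0.995),  # train
    `8` = list(sd = 0.38, phi = 0.985)   # subway
  )
}

# Dynamic-class gait multipliers on the user fundamental / amplitude.
dynamic_signal_params <- function() {
  list(
    `2` = list(fmult = 1.00, amult = 1.0),  # walk
    `3` = list(fmult = 1.45, amult = 2.0),  # run
    `4` = list(fmult = 0.75, amult = 0.8)   # bike
  )
}

draw_activity_sequence <- function(n_samples, fs, mean_dwell, class_mix) {
  labels <- integer(n_samples)
  pos <- 1L
  current <- sample.int(8L, 1L, prob = class_mix)
  while (pos <= n_samples) {
    dwell <- max(1L, as.integer(round(rexp(1, rate = 1 / mean_dwell) * fs)))
    end <- min(n_samples, pos + dwell - 1L)
    labels[pos:end] <- current
    pos <- end + 1L
    nxt_prob <- class_mix
    nxt_prob[current] <- 0
    if (sum(nxt_prob) > 0) current <- sample.int(8L, 1L, prob = nxt_prob)
  }
  labels
}

# AR(1) series with stationary sd `sd` and coefficient `phi`.
ar1_series <- function(n, sd, phi) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(rnorm(n, sd = innov_sd), phi,
                           method = "recursive"))
}

#' Generate a labeled, domain-shifted synthetic sensor session
#'
#' Simulates a challenge-style recording: a sticky semi-Markov activity
#' sequence (exponential dwell times, mean `mean_dwell` seconds), per-sample
#' labels, and 20 channels of synthetic signal segmented into fixed-length
#' windows. Dynamic activities (walk, run, bike) produce quasi-periodic
#' acceleration built from three harmonics of the user's gait fundamental;
#' vehicle activities (still, car, bus, train, subway) produce low-amplitude
#' AR(1) vibration shared across body locations. Location rotation and gain
#' are applied at full strength to dynamic-activity samples and at one quarter
#' strength to vehicle-activity samples, so the location shift is strong where
#' human movement dominates and weak where vehicle vibration dominates. The
#' gravity channel always has norm 9.81 and orientation quaternions are
#' unit-norm.
#'
#' Two sessions generated with the same `config` but different `domain`s share
#' the same underlying activity sequence and body-frame signal, so they
#' emulate the same recording observed at two phone placements.
#'
#' @param config A [session_config()].
#' @param domain A [domain_spec()].
#' @return A `window_set`: list with `windows` (list of 20 x samples
#'   matrices), `labels` (windows x samples integer matrix of per-sample
#'   labels), `domain`, `order_key` (true temporal index per window),
#'   `sample_rate`, `window_len`.
#' @examples
#' ws <- generate_session(session_config(seed = 1, duration = 60))
#' length(ws$windows)
#' @export
generate_session <- function(config = session_config(),
                             domain = domain_spec()) {
  stopifnot(inherits(config, "session_config"), inherits(domain, "domain_spec"))
  fs <- config$sample_rate
  n <- as.integer(round(config$duration * fs))
  spw <- as.integer(round(fs * config$window_len))
  n_win <- n %/% spw

  with_seed(config$seed, {
    labels <- draw_activity_sequence(n, fs, config$mean_dwell, config$class_mix)
    t <- (seq_len(n) - 1) / fs
    noise_sd <- config$noise_sd

    # body-frame linear acceleration and angular velocity
    lacc <- matrix(rnorm(3 * n, sd = noise_sd), nrow = 3)
    gyr <- matrix(rnorm(3 * n, sd = noise_sd), nrow = 3)
    dyn_par <- dynamic_signal_params()
    veh_par <- vehicle_signal_params()
    for (a in unique(labels)) {
      idx <- which(labels == a)
      if (a %in% dynamic_codes()) {
        p <- dyn_par[[as.character(a)]]
        f0 <- domain$user_gait_freq * p$fmult
        # slow amplitude and phase drift: human gait is quasi-periodic, not
        # metronomic (also prevents windows from being exact periodic copies)
        amp <- domain$user_gait_amp * p$amult *
          (1 + 0.15 * sin(2 * pi * 0.05 * t[idx] + a))
        ph <- 2 * pi * f0 * t[idx] + 0.3 * sin(2 * pi * 0.07 * t[idx] + 2 * a)
        lacc[3, idx] <- lacc[3, idx] + amp *
          (sin(ph) + 0.4 * sin(2 * ph + 0.7) + 0.2 * sin(3 * ph + 1.9))
        lacc[1, idx] <- lacc[1, idx] + 0.5 * amp * sin(ph + 1.0)
        lacc[2, idx] <- lacc[2, idx] + 0.3 * amp * sin(ph + 2.1)
        gyr[1, idx] <- gyr[1, idx] + 0.6 * p$amult * sin(ph + 0.4)
        gyr[2, idx] <- gyr[2, idx] + 0.4 * p$amult * sin(2 * ph + 1.2)
      } else {
        p <- veh_par[[as.character(a)]]
        for (ax in 1:3) {
          lacc[ax, idx] <- lacc[ax, idx] +
            ar1_series(length(idx), p$sd * c(0.8, 0.9, 1.0)[ax], p$phi)
        }
        for (ax in 1:3) {
          gyr[ax, idx] <- gyr[ax, idx] +
            ar1_series(length(idx), 0.1 * p$sd, 0.99)
        }
      }
    }

    # transient disturbances (road bumps, handling): damped 9 Hz
    # oscillations at Poisson times, skipped while stationary
    n_bumps <- stats::rpois(1, config$bump_rate * config$duration)
    if (n_bumps > 0) {
      onsets <- sort(sample.int(n, n_bumps, replace = TRUE))
      wave_len <- as.integer(0.3 * fs)
      tw <- (seq_len(wave_len) - 1) / fs
      base_wave <- exp(-tw / 0.08) * sin(2 * pi * 9 * tw)
      for (o in onsets) {
        if (labels[o] == 1L) next
        amp <- rnorm(1, sd = config$bump_amp)
        dir <- rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        span <- o:min(n, o + wave_len - 1L)
        lacc[, span] <- lacc[, span] +
          (amp * dir) %o% base_wave[seq_along(span)]
      }
    }

    # location transform: full strength on dynamic samples, quarter strength
    # on vehicle samples
    R_full <- axis_angle_rotation(domain$rotation_axis, domain$rotation_angle)
    R_att <- axis_angle_rotation(domain$rotation_axis,
                                 0.25 * domain$rotation_angle)
    g_full <- domain$location_gain
    g_att <- 1 + 0.25 * (domain$location_gain - 1)
    dyn_mask <- labels %in% dynamic_codes()

    transform3 <- function(m, gain = TRUE) {
      out <- matrix(0, 3, n)
      if (any(dyn_mask)) {
        out[, dyn_mask] <- (if (gain) g_full else 1) * (R_full %*% m[, dyn_mask, drop = FALSE])
      }
      if (any(!dyn_mask)) {
        out[, !dyn_mask] <- (if (gain) g_att else 1) * (R_att %*% m[, !dyn_mask, drop = FALSE])
      }
      out
    }

    g_body <- matrix(c(0, 0, 9.81), 3, n)
    gra <- transform3(g_body, gain = FALSE)
    lacc_w <- transform3(lacc)
    acc <- gra + lacc_w
    gyr_w <- transform3(gyr)
    B <- matrix(c(22, 5, -42), 3, n)
    mag <- transform3(B, gain = FALSE) + matrix(rnorm(3 * n, sd = noise_sd), 3)

    q_full <- rotation_to_quaternion(R_full)
    q_att <- rotation_to_quaternion(R_att)
    ori <- matrix(q_att, 4, n)
    if (any(dyn_mask)) ori[, dyn_mask] <- q_full

    # barometric channel: slow weather/altitude drift plus sensor random
    # walk; barometers are much quieter than IMUs, so their white-noise
    # floor is mostly fixed, with only a weak coupling to the overall
    # sensor-quality level
    pressure <- matrix(1013.25 + 0.01 * t + cumsum(rnorm(n, sd = 5e-4)) +
                         rnorm(n, sd = 2e-3 + 0.02 * noise_sd), 1, n)

    sig <- rbind(acc, gra, lacc_w, gyr_w, mag, ori, pressure)
    rownames(sig) <- channel_names()

    windows <- lapply(seq_len(n_win), function(i) {
      sig[, ((i - 1) * spw + 1):(i * spw), drop = FALSE]
    })
    label_mat <- matrix(labels[seq_len(n_win * spw)], nrow = n_win,
                        ncol = spw, byrow = TRUE)

    new_window_set(windows, label_mat, domain, seq_len(n_win),
                   fs, config$window_len)
  })
}

new_window_set <- function(windows, labels, domain, order_key,
                           sample_rate, window_len) {
  structure(
    list(
      windows = windows, labels = labels, domain = domain,
      order_key = as.integer(order_key), sample_rate = sample_rate,
      window_len = window_len
    ),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "<window_set> %d windows of %d channels x %d samples (%g Hz, %gs)\n",
    length(x$windows), nrow(x$windows[[1]]), ncol(x$windows[[1]]),
    x$sample_rate, x$window_len
  ))
  cat(sprintf("  domain: location=%s user=%d\n",
              x$domain$location, x$domain$user))
  invisible(x)
}

#' Randomly shuffle the windows of a session
#'
#' Permutes windows uniformly at random, emulating a shuffled evaluation set.
#' The `order_key` element carries each window's true temporal index, so
#' sorting the shuffled set by `order_key` restores the original sequence and
#' re-ordering algorithms can be scored against the truth.
#'
#' @param ws A `window_set`.
#' @param seed Integer seed for the permutation.
#' @return The permuted `window_set`.
#' @export
shuffle_windows <- function(ws, seed = 1L) {
  stopifnot(inherits(ws, "window_set"))
  n <- length(ws$windows)
  if (n < 1) abort("window set is empty")
  perm <- with_seed(seed, sample.int(n))
  new_window_set(
    ws$windows[perm], ws$labels[perm, , drop = FALSE], ws$domain,
    ws$order_key[perm], ws$sample_rate, ws$window_len
  )
}

#' Extract the per-window (majority) label sequence of a window set
#'
#' @param ws A `window_set`.
#' @return Integer vector of modal per-window labels, in the set's current
#'   window order.
#' @export
window_labels <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  apply(ws$labels, 1, window_label)
}
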