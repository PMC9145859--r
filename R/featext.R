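#' Majority label of a window
#'
#' The per-window label is the most frequent per-sample label; ties break
#' toward the lowest class code.
#'
#' @param per_sample_labels Nonempty integer vector of codes in 1..8.
#' @return A single integer class code.
#' @export
window_label <- function(per_sample_labels) {
  if (length(per_sample_labels) == 0) abort("empty label vector")
  check_labels(per_sample_labels)
  counts <- tabulate(per_sample_labels, nbins = 8L)
  which.max(counts) # first maximum = lowest code on ties
}

#' Welch power spectral density estimate
#'
#' Averages Hann-windowed, 50%-overlapping segment periodograms. With the
#' default 2-second segments at 50 Hz the bin width is 0.5 Hz.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param segment_sec Segment length in seconds.
#' @param overlap Fractional overlap between consecutive segments.
#' @return A list with `freq` (Hz) and `psd` (one-sided density) vectors.
#' @export
welch_psd <- function(x, fs, segment_sec = 2, overlap = 0.5) {
  nperseg <- as.integer(round(segment_sec * fs))
  if (length(x) < nperseg) {
    abort("window shorter than one Welch segment")
  }
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nperseg + 1L, by = step)
  if (length(starts) < 2) abort("fewer than two Welch segments fit the window")
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1)) # Hann
  scale <- 1 / (fs * sum(win^2))
  n_freq <- nperseg %/% 2 + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- abs(fft(seg)[seq_len(n_freq)])^2 * scale
    # one-sided: double all bins except DC (and Nyquist for even nperseg)
    dbl <- rep(2, n_freq); dbl[1] <- 1
    if (nperseg %% 2 == 0) dbl[n_freq] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(n_freq) - 1) * fs / nperseg,
       psd = acc / length(starts))
}

#' Frequency-domain features of one channel
#'
#' From the Welch PSD of the signal: the three largest spectral magnitudes
#' (sorted descending), the spectral entropy of the normalised PSD in nats,
#' and the spectral energy (sum of PSD bins). An all-zero signal yields all
#' zeros, with entropy defined as 0.
#'
#' @inheritParams welch_psd
#' @return A named numeric vector `mag1`, `mag2`, `mag3`, `entropy`,
#'   `energy`.
#' @export
frequency_features <- function(x, fs, segment_sec = 2, overlap = 0.5) {
  w <- welch_psd(x, fs, segment_sec, overlap)
  total <- sum(w$psd)
  mags <- sort(w$psd, decreasing = TRUE)[1:3]
  entropy <- 0
  if (total > 0) {
    p <- w$psd / total
    p <- p[p > 0]
    entropy <- -sum(p * log(p))
  } else {
    mags <- c(0, 0, 0)
  }
  c(mag1 = mags[1], mag2 = mags[2], mag3 = mags[3],
    entropy = entropy, energy = total)
}

# Autocorrelation at lag k using the global mean/variance estimator; 0 for
# zero-variance signals or lags >= length.
autocorrelation <- function(x, k) {
  n <- length(x)
  if (k >= n) return(0)
  mu <- mean(x)
  v <- sum((x - mu)^2)
  if (v == 0) return(0)
  sum((x[1:(n - k)] - mu) * (x[(k + 1):n] - mu)) / v
}

#' Time-domain features of one channel
#'
#' Minimum, maximum, standard deviation, counts of samples strictly above and
#' below the signal mean, mean change and mean absolute change of successive
#' samples, and autocorrelations at the given lags (0 for zero-variance
#' signals).
#'
#' @param x Numeric signal.
#' @param lags Integer autocorrelation lags, in samples.
#' @return A named numeric vector.
#' @export
time_features <- function(x, lags = c(1L, 10L, 25L)) {
  if (length(x) == 0) abort("empty signal")
  mu <- mean(x)
  d <- if (length(x) > 1) diff(x) else 0
  ac <- vapply(lags, function(k) autocorrelation(x, k), numeric(1))
  names(ac) <- paste0("autocorr_", lags)
  c(
    min = min(x), max = max(x), sd = sd_or_zero(x),
    count_above_mean = sum(x > mu), count_below_mean = sum(x < mu),
    mean_change = mean(d), mean_abs_change = mean(abs(d)),
    ac
  )
}

sd_or_zero <- function(x) if (length(x) > 1) sd(x) else 0

# Expert accelerometer features: mean-crossing rate, band-passed peak count,
# interquartile range, kurtosis, skewness. Undefined moments (constant
# signal) are imputed as 0.
expert_channel_features <- function(x, fs) {
  ctr <- x - mean(x)
  sgn <- sign(ctr[ctr != 0])
  zcr <- if (length(sgn) > 1) sum(diff(sgn) != 0) else 0
  bp <- as.numeric(signal::filter(iir_coefficients(filter_spec("bandpass"), fs), x))
  bpc <- bp - mean(bp)
  up <- sum(bpc[-length(bpc)] <= 0 & bpc[-1] > 0) # upward mean crossings
  kur <- e1071::kurtosis(x)
  skw <- e1071::skewness(x)
  c(
    zero_cross = zcr, peak_count = up,
    iqr = as.numeric(diff(quantile(x, c(0.25, 0.75)))),
    kurtosis = if (is.finite(kur)) kur else 0,
    skewness = if (is.finite(skw)) skw else 0
  )
}

#' Feature extraction specification
#'
#' Controls which features [extract_features()] computes. The default
#' specification applies frequency- and time-domain features to all 28
#' preprocessed channels and an expert accelerometer set (mean-crossing
#' rate, band-passed peak count, interquartile range, kurtosis, skewness,
#' plus per-axis correlations) to acceleration-derived channels only, where
#' these features have a physical interpretation.
#'
#' @param segment_sec,overlap Welch parameters (see [welch_psd()]).
#' @param lags Autocorrelation lags in samples.
#' @param expert_channels Channels receiving the expert accelerometer set.
#' @param corr_groups Named list of triaxial channel triples whose pairwise
#'   axis correlations are added.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(segment_sec = 2, overlap = 0.5,
                         lags = c(1L, 10L, 25L),
                         expert_channels = c(
                           "Acc_x", "Acc_y", "Acc_z", "Acc_mag",
                           "LAcc_x", "LAcc_y", "LAcc_z", "LAcc_mag"
                         ),
                         corr_groups = list(
                           Acc = c("Acc_x", "Acc_y", "Acc_z"),
                           LAcc = c("LAcc_x", "LAcc_y", "LAcc_z")
                         )) {
  structure(
    list(segment_sec = segment_sec, overlap = overlap, lags = lags,
         expert_channels = expert_channels, corr_groups = corr_groups),
    class = "feature_spec"
  )
}

#' Number of features produced by a specification
#'
#' @param spec A [feature_spec()].
#' @param n_channels Number of channels in the preprocessed windows.
#' @return Integer feature count.
#' @export
feature_count <- function(spec = feature_spec(), n_channels = 28L) {
  per_channel <- 5L + 7L + length(spec$lags)
  n_channels * per_channel + 5L * length(spec$expert_channels) +
    3L * length(spec$corr_groups)
}

window_features <- function(w, fs, spec) {
  chans <- rownames(w)
  out <- numeric(0)
  for (ch in chans) {
    x <- w[ch, ]
    f <- c(frequency_features(x, fs, spec$segment_sec, spec$overlap),
           time_features(x, spec$lags))
    names(f) <- paste0(ch, "_", names(f))
    out <- c(out, f)
  }
  for (ch in spec$expert_channels) {
    f <- expert_channel_features(w[ch, ], fs)
    names(f) <- paste0(ch, "_", names(f))
    out <- c(out, f)
  }
  for (g in names(spec$corr_groups)) {
    trio <- spec$corr_groups[[g]]
    prs <- utils::combn(3, 2)
    f <- apply(prs, 2, function(ij) {
      a <- w[trio[ij[1]], ]; b <- w[trio[ij[2]], ]
      if (sd_or_zero(a) == 0 || sd_or_zero(b) == 0) 0 else cor(a, b)
    })
    names(f) <- paste0(g, "_corr_", apply(prs, 2, paste, collapse = ""))
    out <- c(out, f)
  }
  out[!is.finite(out)] <- 0
  out
}

#' Extract a feature table from a preprocessed window set
#'
#' Computes the full feature vector for every window and returns a tidy
#' feature table: one row per window with the window id, its true temporal
#' index, the majority activity label, the domain tags (location, user), and
#' the feature columns in a deterministic order. Features are a pure function
#' of the signals; labels are attached but never read during extraction. Any
#' undefined feature value (for example a correlation of a constant signal)
#' is imputed as 0, so the table is free of `NA`/`Inf`.
#'
#' @param ws A preprocessed `window_set` (virtual streams derived; typically
#'   decimated to 50 Hz).
#' @param spec A [feature_spec()].
#' @return A tibble with columns `window_id`, `order_key`, `label`,
#'   `location`, `user`, then one column per feature.
#' @export
extract_features <- function(ws, spec = feature_spec()) {
  stopifnot(inherits(ws, "window_set"), inherits(spec, "feature_spec"))
  chans <- rownames(ws$windows[[1]])
  missing <- setdiff(unique(c(spec$expert_channels, unlist(spec$corr_groups))),
                     chans)
  if (length(missing) > 0) {
    abort(sprintf("windows lack required channel(s): %s (run derive_virtual_streams()?)",
                  paste(missing, collapse = ", ")))
  }
  feats <- do.call(rbind, lapply(ws$windows, window_features,
                                 fs = ws$sample_rate, spec = spec))
  tibble::as_tibble(feats) %>%
    mutate(
      window_id = seq_len(length(ws$windows)),
      order_key = ws$order_key,
      label = window_labels(ws),
      location = ws$domain$location,
      user = ws$domain$user,
      .before = 1
    )
}

#' Names of the feature columns of a feature table
#'
#' @param ft A feature table as returned by [extract_features()].
#' @return Character vector of feature column names (everything except the
#'   id/label/domain columns).
#' @export
feature_names <- function(ft) {
  setdiff(names(ft),
          c("window_id", "order_key", "label", "location", "user", "session"))
}

#' Per-session label sequences of a feature table, in temporal order
#'
#' @param ft A feature table; rows are grouped by the optional `session`
#'   column and ordered by `order_key` within each session.
#' @return A list of integer label sequences.
#' @export
label_sequences <- function(ft) {
  if ("session" %in% names(ft)) {
    lapply(split(seq_len(nrow(ft)), ft$session), function(ix) {
      ft$label[ix][order(ft$order_key[ix])]
    })
  } else {
    list(ft$label[order(ft$order_key)])
  }
}
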