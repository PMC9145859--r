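#' Specify an IIR filter
#'
#' Butterworth IIR designs used for preprocessing. Defaults follow the
#' package's preprocessing conventions: a 2nd-order low-pass at 10 Hz to
#' remove high-frequency noise, and a 2nd-order band-pass at 0.3-8 Hz that
#' brackets the human-movement band while rejecting the gravity/DC component.
#' Filtering is causal single-pass (matches streaming use).
#'
#' @param kind `"lowpass"` or `"bandpass"`.
#' @param cutoff Cutoff frequency in Hz (low-pass) or length-2 `c(low, high)`
#'   (band-pass). Must lie strictly inside (0, Nyquist) at filter time.
#' @param order Filter order (per band edge for the band-pass).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("lowpass", "bandpass"), cutoff = NULL,
                        order = 2L) {
  kind <- match.arg(kind)
  cutoff <- cutoff %||% switch(kind, lowpass = 10, bandpass = c(0.3, 8))
  if (kind == "bandpass") {
    if (length(cutoff) != 2 || cutoff[1] >= cutoff[2]) {
      abort("bandpass cutoff must be c(low, high) with low < high")
    }
  } else if (length(cutoff) != 1) {
    abort("lowpass cutoff must be a single frequency")
  }
  if (any(cutoff <= 0)) abort("cutoffs must be positive")
  structure(list(kind = kind, cutoff = cutoff, order = as.integer(order)),
            class = "filter_spec")
}

iir_coefficients <- function(spec, sample_rate) {
  nyq <- sample_rate / 2
  if (any(spec$cutoff >= nyq)) {
    abort(sprintf("cutoff must be below the Nyquist frequency (%g Hz)", nyq))
  }
  type <- switch(spec$kind, lowpass = "low", bandpass = "pass")
  signal::butter(spec$order, spec$cutoff / nyq, type = type)
}

#' Apply a causal IIR filter to signal data
#'
#' Filters each channel independently with a causal, single-pass Butterworth
#' filter. Low-pass designs pass DC with unit gain; band-pass designs
#' attenuate DC essentially completely.
#'
#' @param x A numeric vector, a channels x samples matrix, or a `window_set`
#'   (filtered window by window).
#' @param spec A [filter_spec()].
#' @param sample_rate Sampling rate in Hz (taken from the object for a
#'   `window_set`).
#' @return Same shape as the input.
#' @export
apply_iir <- function(x, spec = filter_spec(), sample_rate = 100) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(x, "window_set")) {
    flt <- iir_coefficients(spec, x$sample_rate)
    x$windows <- lapply(x$windows, filter_matrix, flt = flt)
    return(x)
  }
  flt <- iir_coefficients(spec, sample_rate)
  if (is.matrix(x)) filter_matrix(x, flt) else
    as.numeric(signal::filter(flt, x))
}

filter_matrix <- function(m, flt) {
  out <- t(apply(m, 1, function(row) as.numeric(signal::filter(flt, row))))
  dimnames(out) <- dimnames(m)
  out
}

#' Decimate a 100 Hz window set to 50 Hz
#'
#' Applies an 8th-order Butterworth anti-alias low-pass at 22 Hz
#' (zero-phase, with reflection padding to suppress edge transients — the
#' standard decimation practice), then keeps every second sample.
#' Orientation quaternion rows are renormalised to unit norm afterwards.
#' Per-sample labels are subsampled in step.
#'
#' @param ws A `window_set` sampled at 100 Hz with an even per-window sample
#'   count, or a channels x samples matrix (assumed 100 Hz).
#' @return The decimated object at 50 Hz with half the samples per window.
#' @export
decimate_to_50hz <- function(ws) {
  if (is.matrix(ws)) {
    if (ncol(ws) %% 2 != 0) abort("sample count must be even")
    return(decimate_matrix(ws))
  }
  stopifnot(inherits(ws, "window_set"))
  if (ws$sample_rate != 100) abort("input must be sampled at 100 Hz")
  spw <- ncol(ws$windows[[1]])
  if (spw %% 2 != 0) abort("sample count must be even")
  keep <- seq(1, spw, by = 2)
  ws$windows <- lapply(ws$windows, decimate_matrix)
  ws$labels <- ws$labels[, keep, drop = FALSE]
  ws$sample_rate <- 50
  ws
}

decimate_matrix <- function(m) {
  # anti-alias below the new Nyquist (25 Hz) before subsampling
  flt <- signal::butter(8, 22 / 50, type = "low")
  keep <- seq(1, ncol(m), by = 2)
  out <- t(apply(m, 1, zero_phase_filter, flt = flt))[, keep, drop = FALSE]
  dimnames(out) <- list(rownames(m), NULL)
  ori <- paste0("Ori_", c("w", "x", "y", "z"))
  if (all(ori %in% rownames(out))) {
    nrm <- sqrt(colSums(out[ori, , drop = FALSE]^2))
    nrm[nrm == 0] <- 1
    out[ori, ] <- sweep(out[ori, , drop = FALSE], 2, nrm, "/")
  }
  out
}

# Zero-phase filtering with odd reflection padding at both ends (keeps
# constants exact and avoids startup transients).
zero_phase_filter <- function(x, flt) {
  n <- length(x)
  npad <- min(n - 1, 100)
  if (npad < 1) return(x)
  pre <- 2 * x[1] - rev(x[2:(npad + 1)])
  post <- 2 * x[n] - rev(x[(n - npad):(n - 1)])
  y <- signal::filtfilt(flt, c(pre, x, post))
  y[(npad + 1):(npad + n)]
}

#' Euclidean norm of a triaxial signal
#'
#' @param triaxial A 3 x samples matrix.
#' @return A length-`samples` nonnegative vector of elementwise norms.
#' @examples
#' magnitude(matrix(c(3, 4, 0), nrow = 3))
#' @export
magnitude <- function(triaxial) {
  if (!is.matrix(triaxial) || nrow(triaxial) != 3) {
    abort("magnitude() expects a 3 x samples matrix")
  }
  sqrt(colSums(triaxial^2))
}

#' Convert a quaternion stream to Euler angles
#'
#' Uses the intrinsic z-y'-x'' (yaw-pitch-roll) convention. Quaternions with
#' norm in [0.9, 1.1] are renormalised; anything further from unit norm is an
#' error.
#'
#' @param q A 4 x samples matrix with rows (w, x, y, z), or a length-4 vector.
#' @return A 3 x samples matrix with rows `roll`, `pitch`, `yaw` in radians;
#'   pitch lies in \[-pi/2, pi/2\].
#' @export
quat_to_euler <- function(q) {
  if (is.numeric(q) && is.null(dim(q)) && length(q) == 4) q <- matrix(q, 4, 1)
  if (!is.matrix(q) || nrow(q) != 4) {
    abort("quat_to_euler() expects a 4 x samples matrix (w, x, y, z)")
  }
  nrm <- sqrt(colSums(q^2))
  if (any(nrm < 0.9 | nrm > 1.1)) {
    abort("quaternion norms outside [0.9, 1.1]; refusing to renormalise")
  }
  q <- sweep(q, 2, nrm, "/")
  w <- q[1, ]; x <- q[2, ]; y <- q[3, ]; z <- q[4, ]
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))
  pitch <- asin(pmin(1, pmax(-1, 2 * (w * y - z * x))))
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
  out <- rbind(roll = roll, pitch = pitch, yaw = yaw)
  out
}

virtual_stream_names <- function() {
  c("Acc_mag", "LAcc_mag", "Gra_mag", "Mag_mag", "Gyr_mag",
    "Ori_roll", "Ori_pitch", "Ori_yaw")
}

#' Append virtual sensor streams to a window set
#'
#' Derives 8 additional channels from the 20 raw ones: the Euclidean
#' magnitudes of the five triaxial sensors (acceleration, linear
#' acceleration, gravity, magnetic field, angular velocity) and the three
#' Euler angles of the orientation quaternion. The derived streams are
#' treated downstream exactly like raw channels.
#'
#' @param ws A `window_set` with the 20 standard channels.
#' @return The `window_set` with 28 channels per window.
#' @export
derive_virtual_streams <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  chans <- rownames(ws$windows[[1]])
  if (any(virtual_stream_names() %in% chans)) {
    abort("virtual streams already derived (28-channel input)")
  }
  triaxial <- list(
    Acc_mag = c("Acc_x", "Acc_y", "Acc_z"),
    LAcc_mag = c("LAcc_x", "LAcc_y", "LAcc_z"),
    Gra_mag = c("Gra_x", "Gra_y", "Gra_z"),
    Mag_mag = c("Mag_x", "Mag_y", "Mag_z"),
    Gyr_mag = c("Gyr_x", "Gyr_y", "Gyr_z")
  )
  needed <- c(unlist(triaxial), paste0("Ori_", c("w", "x", "y", "z")))
  missing <- setdiff(needed, chans)
  if (length(missing) > 0) {
    abort(sprintf("missing source channel(s): %s",
                  paste(missing, collapse = ", ")))
  }
  ws$windows <- lapply(ws$windows, function(w) {
    mags <- do.call(rbind, lapply(triaxial, function(src) {
      magnitude(w[src, , drop = FALSE])
    }))
    euler <- quat_to_euler(w[paste0("Ori_", c("w", "x", "y", "z")), ,
                             drop = FALSE])
    rownames(euler) <- c("Ori_roll", "Ori_pitch", "Ori_yaw")
    rbind(w, mags, euler)
  })
  ws
}
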