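#' Write / read a window set in challenge text layout
#'
#' The on-disk layout mirrors the public locomotion-challenge releases: one
#' whitespace-separated text file per channel (`Acc_x.txt` ... `Pressure.txt`)
#' with one row per window, a `Label.txt` with one integer per sample in the
#' same row layout, and a `session.json` sidecar holding the domain metadata
#' and the true temporal order key.
#'
#' @param ws A `window_set`.
#' @param directory Target directory (created if missing).
#' @return `write_challenge_format()` returns the directory invisibly;
#'   `read_challenge_format()` returns a `window_set`. Values survive the
#'   round trip to at least 6 significant digits, labels exactly.
#' @export
write_challenge_format <- function(ws, directory) {
  stopifnot(inherits(ws, "window_set"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  chans <- rownames(ws$windows[[1]])
  for (ci in seq_along(chans)) {
    rows <- vapply(ws$windows, function(w) {
      paste(formatC(w[ci, ], format = "g", digits = 8), collapse = " ")
    }, character(1))
    writeLines(rows, file.path(directory, paste0(chans[ci], ".txt")))
  }
  label_rows <- apply(ws$labels, 1, paste, collapse = " ")
  writeLines(label_rows, file.path(directory, "Label.txt"))
  sidecar <- list(
    location = ws$domain$location, user = ws$domain$user,
    location_gain = ws$domain$location_gain,
    rotation_angle = ws$domain$rotation_angle,
    rotation_axis = ws$domain$rotation_axis,
    user_gait_freq = ws$domain$user_gait_freq,
    user_gait_amp = ws$domain$user_gait_amp,
    order_key = ws$order_key,
    sample_rate = ws$sample_rate, window_len = ws$window_len
  )
  jsonlite::write_json(sidecar, file.path(directory, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

read_rows <- function(path, expected_len = NULL) {
  fname <- basename(path)
  if (!file.exists(path)) {
    abort(sprintf("missing channel file: %s", fname))
  }
  lines <- readLines(path)
  rows <- lapply(seq_along(lines), function(i) {
    vals <- as.numeric(strsplit(trimws(lines[[i]]), "\\s+")[[1]])
    if (!is.null(expected_len) && length(vals) != expected_len) {
      abort(sprintf("format error in %s, row %d: expected %d values, found %d",
                    fname, i, expected_len, length(vals)))
    }
    vals
  })
  do.call(rbind, rows)
}

#' @rdname write_challenge_format
#' @export
read_challenge_format <- function(directory) {
  side_path <- file.path(directory, "session.json")
  if (!file.exists(side_path)) abort("missing sidecar file: session.json")
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  spw <- as.integer(round(side$sample_rate * side$window_len))
  chans <- channel_names()
  mats <- lapply(chans, function(ch) {
    read_rows(file.path(directory, paste0(ch, ".txt")), spw)
  })
  n_win <- unique(vapply(mats, nrow, integer(1)))
  if (length(n_win) != 1) {
    abort("format error: channel files disagree on window count")
  }
  label_mat <- read_rows(file.path(directory, "Label.txt"), spw)
  if (nrow(label_mat) != n_win) {
    abort(sprintf("format error in Label.txt: %d rows, expected %d",
                  nrow(label_mat), n_win))
  }
  storage.mode(label_mat) <- "integer"
  windows <- lapply(seq_len(n_win), function(i) {
    w <- do.call(rbind, lapply(mats, function(m) m[i, ]))
    rownames(w) <- chans
    w
  })
  domain <- domain_spec(
    location = side$location, user = side$user,
    location_gain = side$location_gain,
    rotation_angle = side$rotation_angle,
    rotation_axis = unlist(side$rotation_axis),
    user_gait_freq = side$user_gait_freq,
    user_gait_amp = side$user_gait_amp
  )
  new_window_set(windows, label_mat, domain, unlist(side$order_key),
                 side$sample_rate, side$window_len)
}
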