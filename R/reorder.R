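#' Configure the window re-ordering algorithm
#'
#' Shuffled five-second windows are rejoined by matching the end of one
#' window to the beginning of another: continuous signals change little
#' across a 10 ms boundary, so the true successor of a window is almost
#' always its nearest neighbour in (weighted) Euclidean distance between the
#' last sample vector of one window and the first sample vector of the next.
#'
#' Defaults when `NULL`: `channel_weights` are the inverse per-channel
#' standard deviations computed on the data (so no channel dominates purely
#' by scale), and `threshold` is the 5th percentile of the boundary distances
#' of randomly sampled ordered window pairs.
#'
#' @param threshold Join cutoff: a candidate successor is accepted only when
#'   its boundary distance is below this value.
#' @param channel_weights Nonnegative per-channel weights applied to squared
#'   coordinate differences.
#' @return An object of class `reorder_config`.
#' @export
reorder_config <- function(threshold = NULL, channel_weights = NULL) {
  if (!is.null(threshold) && threshold <= 0) abort("threshold must be > 0")
  if (!is.null(channel_weights) &&
      (any(channel_weights < 0) || all(channel_weights == 0))) {
    abort("channel_weights must be nonnegative with at least one positive")
  }
  structure(list(threshold = threshold, channel_weights = channel_weights),
            class = "reorder_config")
}

resolve_reorder_config <- function(cfg, ws, seed = 1L) {
  n_chan <- nrow(ws$windows[[1]])
  w <- cfg$channel_weights
  if (is.null(w)) {
    # empirical default: weight each channel by the inverse square of its
    # mean one-sample change, so a genuine one-sample boundary gap costs
    # about 1 per channel while a random pairing costs (sd / step)^2 --
    # smooth, slowly varying channels get the discriminative power
    steps <- rowMeans(abs(do.call(cbind, lapply(ws$windows, function(m) {
      m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
    }))))
    w <- ifelse(steps > 0, 1 / steps^2, 0)
    if (all(w == 0)) w <- rep(1, n_chan)
  }
  if (length(w) != n_chan) abort("channel_weights length must match channels")
  thr <- cfg$threshold
  if (is.null(thr)) {
    n <- length(ws$windows)
    pairs <- with_seed(seed + 1L, {
      cbind(sample.int(n, 200, replace = TRUE),
            sample.int(n, 200, replace = TRUE))
    })
    d <- vapply(seq_len(nrow(pairs)), function(k) {
      boundary_distance(ws$windows[[pairs[k, 1]]], ws$windows[[pairs[k, 2]]],
                        weights = w)
    }, numeric(1))
    thr <- as.numeric(quantile(d, 0.05))
  }
  list(threshold = thr, channel_weights = w)
}

#' Weighted boundary distance between two windows
#'
#' The weighted Euclidean distance between the last sample vector of `a` and
#' the first sample vector of `b` — the cost of placing `b` immediately after
#' `a`. Not symmetric in its arguments.
#'
#' @param a,b Channels x samples matrices with identical channel layout.
#' @param weights Nonnegative per-channel weights (default all 1).
#' @return A nonnegative scalar.
#' @examples
#' a <- matrix(c(0, 0, 1, 0), nrow = 2) # last sample (1, 0)
#' b <- matrix(c(0, 1, 5, 5), nrow = 2) # first sample (0, 1)
#' boundary_distance(a, b) # sqrt(2)
#' @export
boundary_distance <- function(a, b, weights = NULL) {
  if (nrow(a) != nrow(b)) abort("channel layout mismatch between windows")
  weights <- weights %||% rep(1, nrow(a))
  d <- a[, ncol(a)] - b[, 1]
  sqrt(sum(weights * d^2))
}

#' Find the best successor window in a pool
#'
#' Returns the pool member minimising [boundary_distance()] from `current`,
#' with ties broken toward the lowest pool index.
#'
#' @param current Channels x samples matrix whose successor is sought.
#' @param pool Nonempty list of candidate windows.
#' @param weights Per-channel weights passed to [boundary_distance()].
#' @return A list with `index` (position in `pool`) and `distance`.
#' @export
closest_window <- function(current, pool, weights = NULL) {
  if (length(pool) == 0) abort("candidate pool is empty")
  d <- vapply(pool, function(w) boundary_distance(current, w, weights),
              numeric(1))
  i <- which.min(d) # which.min returns the first (lowest-index) minimum
  list(index = i, distance = d[[i]])
}

#' Greedily rejoin shuffled windows into locally ordered chains
#'
#' Greedy segment joining: every window starts as a one-window segment; a
#' (seeded) random segment is repeatedly extended by joining on the segment
#' whose first sample best matches the current segment's last sample, while
#' that boundary distance stays below the threshold. When a segment's end
#' finds no sufficiently close continuation it is set aside — but it remains
#' available as a continuation *of other segments*, so a chain is only final
#' once no segment pair can be joined. Every window ends up in exactly one
#' chain. Chains are locally ordered; the ordering *between* chains is
#' unknown and not attempted.
#'
#' Candidate ties break toward the segment whose head has the lowest window
#' index, making the joined-pair set deterministic given the seed; on
#' unambiguous data the joined-pair set is the same for every seed (only the
#' order in which chains are assembled differs).
#'
#' @param ws A `window_set` (typically shuffled; distances are computed on
#'   the full-rate signal).
#' @param cfg A [reorder_config()]; `NULL` entries are resolved from the data.
#' @param seed Seed controlling the random segment choices.
#' @return An object of class `reorder_result`: list with `chains` (list of
#'   integer index vectors into `ws`), `boundary_distances` (per chain, one
#'   fewer than its length), `threshold`, `channel_weights`. Use
#'   [chain_table()] for a tidy view.
#' @export
reorder_data <- function(ws, cfg = reorder_config(), seed = 1L) {
  stopifnot(inherits(ws, "window_set"), inherits(cfg, "reorder_config"))
  n <- length(ws$windows)
  if (n < 1) abort("window set is empty")
  rc <- resolve_reorder_config(cfg, ws, seed)
  w <- rc$channel_weights
  heads <- do.call(cbind, lapply(ws$windows, function(m) m[, 1]))
  tails <- do.call(cbind, lapply(ws$windows, function(m) m[, ncol(m)]))

  segs <- as.list(seq_len(n))      # each segment: window indices in order
  dists <- rep(list(numeric(0)), n)
  alive <- rep(TRUE, n)
  stuck <- rep(FALSE, n)
  with_seed(seed, {
    repeat {
      open <- which(alive & !stuck)
      if (length(open) == 0) break
      cur <- open[[sample.int(length(open), 1)]]
      repeat {
        cand <- setdiff(which(alive), cur)
        if (length(cand) == 0) {
          stuck[cur] <- TRUE
          break
        }
        # order candidates by head window index for a deterministic tie-break
        cand <- cand[order(vapply(segs[cand], function(s) s[1], integer(1)))]
        tail_vec <- tails[, segs[[cur]][length(segs[[cur]])]]
        d <- sqrt(colSums(w * (heads[, vapply(segs[cand], function(s) s[1],
                                              integer(1)), drop = FALSE] -
                                 tail_vec)^2))
        j <- cand[[which.min(d)]]
        if (min(d) < rc$threshold) {
          dists[[cur]] <- c(dists[[cur]], min(d), dists[[j]])
          segs[[cur]] <- c(segs[[cur]], segs[[j]])
          stuck[cur] <- stuck[j]
          alive[j] <- FALSE
          if (stuck[cur]) break
        } else {
          stuck[cur] <- TRUE
          break
        }
      }
    }
  })
  keep <- which(alive)
  structure(
    list(chains = segs[keep], boundary_distances = dists[keep],
         threshold = rc$threshold, channel_weights = w),
    class = "reorder_result"
  )
}

#' @export
print.reorder_result <- function(x, ...) {
  lens <- lengths(x$chains)
  cat(sprintf("<reorder_result> %d chains over %d windows (longest %d)\n",
              length(x$chains), sum(lens), max(lens)))
  invisible(x)
}

#' Tidy chain membership table
#'
#' @param res A `reorder_result`.
#' @return A tibble with columns `window_id`, `chain_id`, `position`.
#' @export
chain_table <- function(res) {
  stopifnot(inherits(res, "reorder_result"))
  purrr::imap_dfr(res$chains, function(ch, i) {
    tibble::tibble(window_id = ch, chain_id = i, position = seq_along(ch))
  })
}

#' Fraction of true adjacencies recovered by a re-ordering
#'
#' Compares the joined pairs of a [reorder_data()] result against the true
#' successor relation recorded in the window set's `order_key`.
#'
#' @param res A `reorder_result`.
#' @param ws The `window_set` the result was computed on.
#' @return A list with `recovered` (count of correctly joined pairs), `total`
#'   (number of true adjacencies present in the set), `fraction`, and
#'   `spurious` (joined pairs that are not true adjacencies).
#' @export
adjacency_recovery <- function(res, ws) {
  key <- ws$order_key
  joined <- purrr::map_dfr(res$chains, function(ch) {
    if (length(ch) < 2) return(tibble::tibble(from = integer(0), to = integer(0)))
    tibble::tibble(from = key[ch[-length(ch)]], to = key[ch[-1]])
  })
  total <- sum((sort(key) + 1) %in% key)
  correct <- sum(joined$to == joined$from + 1)
  list(
    recovered = correct, total = total,
    fraction = if (total > 0) correct / total else NA_real_,
    spurious = nrow(joined) - correct
  )
}
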