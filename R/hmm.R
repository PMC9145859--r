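#' Construct validated HMM parameters
#'
#' The smoothing HMM treats the true activity as the hidden state and the
#' classifier's prediction as the observed symbol. `transition` holds
#' P(next activity | current activity), `emission` holds
#' P(predicted class | true class), and `initial` the state distribution of
#' the first window.
#'
#' @param initial Length-K probability vector.
#' @param transition,emission K x K row-stochastic matrices.
#' @param pseudocount The smoothing pseudocount the matrices were estimated
#'   with (recorded for provenance).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(initial, transition, emission, pseudocount = NA_real_) {
  K <- length(initial)
  check_rows <- function(m, what) {
    if (!is.matrix(m) || any(dim(m) != K)) {
      abort(sprintf("%s must be a %d x %d matrix", what, K, K))
    }
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12)) {
      abort(sprintf("%s rows must be probability distributions", what))
    }
  }
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-12) {
    abort("initial must be a probability vector")
  }
  check_rows(transition, "transition")
  check_rows(emission, "emission")
  structure(list(initial = initial, transition = transition,
                 emission = emission, pseudocount = pseudocount),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("<hmm_params> %d states, pseudocount %s\n",
              length(x$initial), format(x$pseudocount)))
  invisible(x)
}

#' Estimate transition probabilities from label sequences
#'
#' Counts within-sequence transitions (never across sequence boundaries) and
#' row-normalises with additive smoothing:
#' `(count(i -> j) + pseudocount) / (count(i -> .) + K * pseudocount)`.
#' The initial distribution is the smoothed overall label frequency.
#'
#' @param label_sequences A list of integer label sequences (codes 1..K), or
#'   a single vector.
#' @param pseudocount Additive smoothing count (Laplace smoothing at 1).
#' @param n_classes Number of states K.
#' @return A list with `transition` (K x K) and `initial` (length K).
#' @export
estimate_transitions <- function(label_sequences, pseudocount = 1,
                                 n_classes = 8L) {
  if (!is.list(label_sequences)) label_sequences <- list(label_sequences)
  if (length(label_sequences) == 0 || all(lengths(label_sequences) == 0)) {
    abort("no label sequences supplied")
  }
  K <- n_classes
  counts <- matrix(0, K, K)
  freq <- numeric(K)
  for (s in label_sequences) {
    s <- check_labels(s, K)
    freq <- freq + tabulate(s, nbins = K)
    if (length(s) >= 2) {
      from <- s[-length(s)]
      to <- s[-1]
      for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
    }
  }
  smoothed <- counts + pseudocount
  rs <- rowSums(smoothed)
  transition <- smoothed / ifelse(rs > 0, rs, 1)
  zero_rows <- rowSums(counts) == 0 & pseudocount == 0
  transition[zero_rows, ] <- 1 / K # unvisited states: uninformative rows
  initial <- (freq + pseudocount) / sum(freq + pseudocount)
  list(transition = transition, initial = initial)
}

#' Emission probabilities from a classifier confusion matrix
#'
#' Row-normalises the confusion matrix of an analogous classifier (rows true
#' class, columns predicted class) with additive smoothing, giving
#' P(classifier outputs j | true state i).
#'
#' @param cm A K x K confusion matrix of counts.
#' @param pseudocount Additive smoothing count.
#' @return A K x K row-stochastic emission matrix.
#' @export
emissions_from_confusion <- function(cm, pseudocount = 1) {
  check_cm(cm)
  m <- cm + pseudocount
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort("confusion matrix has an all-zero row and pseudocount is 0; increase pseudocount")
  }
  m / rs
}

#' Temporally smooth a prediction sequence with an HMM
#'
#' Decodes the maximum a-posteriori state path (Viterbi, log domain)
#' treating the classifier's predictions as the observed emissions, which
#' corrects isolated misclassifications inconsistent with the sticky
#' activity dynamics. Ties break toward the lower class code. With
#' `method = "posterior"` the per-step posterior mode (forward-backward) is
#' returned instead of the joint MAP path.
#'
#' @param pred_sequence Integer predictions (codes 1..K).
#' @param params An [hmm_params()].
#' @param method `"viterbi"` (default) or `"posterior"`.
#' @return An integer sequence of the same length.
#' @export
smooth_predictions <- function(pred_sequence, params,
                               method = c("viterbi", "posterior")) {
  stopifnot(inherits(params, "hmm_params"))
  method <- match.arg(method)
  K <- length(params$initial)
  obs <- check_labels(pred_sequence, K)
  n <- length(obs)
  if (n == 0) return(integer(0))
  for (o in unique(obs)) {
    if (all(params$emission[, o] == 0)) {
      abort(sprintf(
        "observed symbol %d has zero emission probability in every state; re-estimate with a positive pseudocount", o))
    }
  }
  log_e <- log(params$emission)
  log_t <- log(params$transition)
  log_i <- log(params$initial)
  if (method == "viterbi") {
    delta <- matrix(-Inf, n, K)
    back <- matrix(0L, n, K)
    delta[1, ] <- log_i + log_e[, obs[1]]
    for (t in seq_len(n)[-1]) {
      for (j in seq_len(K)) {
        cand <- delta[t - 1, ] + log_t[, j]
        back[t, j] <- which.max(cand) # first max = lowest code on ties
        delta[t, j] <- cand[back[t, j]] + log_e[j, obs[t]]
      }
    }
    path <- integer(n)
    path[n] <- which.max(delta[n, ])
    for (t in rev(seq_len(n - 1))) path[t] <- back[t + 1, path[t + 1]]
    return(path)
  }
  # forward-backward posterior decoding (scaled, linear domain)
  E <- params$emission; Tm <- params$transition
  alpha <- matrix(0, n, K); beta <- matrix(0, n, K)
  a <- params$initial * E[, obs[1]]
  alpha[1, ] <- a / sum(a)
  for (t in seq_len(n)[-1]) {
    a <- as.numeric(alpha[t - 1, ] %*% Tm) * E[, obs[t]]
    alpha[t, ] <- a / sum(a)
  }
  beta[n, ] <- 1
  for (t in rev(seq_len(n - 1))) {
    b <- as.numeric(Tm %*% (E[, obs[t + 1]] * beta[t + 1, ]))
    beta[t, ] <- b / sum(b)
  }
  post <- alpha * beta
  apply(post, 1, which.max)
}

#' Fit an HMM from cross-validated predictions and training labels
#'
#' The canonical way the smoothing HMM is parameterised: pool the
#' predictions an analogous classifier made across the folds of a
#' cross-validation replica of the pipeline, build the confusion matrix
#' against the fold truths, take row-normalised emissions from it, and
#' estimate transitions and the initial distribution from the (temporally
#' ordered) training label sequences.
#'
#' @param cv_predictions,cv_true_labels Aligned integer vectors pooled over
#'   CV folds.
#' @param train_label_sequences List of training label sequences in temporal
#'   order.
#' @param pseudocount Additive smoothing for both matrices.
#' @param n_classes Number of states K.
#' @return An [hmm_params()] object.
#' @export
fit_secondary_hmm <- function(cv_predictions, cv_true_labels,
                              train_label_sequences, pseudocount = 1,
                              n_classes = 8L) {
  if (length(cv_predictions) != length(cv_true_labels)) {
    abort("cv predictions and labels must be aligned")
  }
  present <- sort(unique(cv_true_labels))
  needed <- sort(unique(unlist(train_label_sequences)))
  if (pseudocount == 0 && !all(needed %in% present)) {
    abort("class absent from CV labels; cannot estimate its emission row")
  }
  cm <- confusion_matrix(cv_true_labels, cv_predictions,
                         classes = seq_len(n_classes))
  emission <- emissions_from_confusion(cm, pseudocount)
  tr <- estimate_transitions(train_label_sequences, pseudocount, n_classes)
  hmm_params(tr$initial, tr$transition, emission, pseudocount)
}
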