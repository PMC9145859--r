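#' Tidy a pipeline result
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return A tibble with one row per pipeline stage: `stage`, `macro_f1`.
#' @export
tidy.pipeline_result <- function(x, ...) x$stages

#' @rdname tidy.pipeline_result
#' @return `glance()`: a one-row tibble with `final_macro_f1`, `n_test`,
#'   `n_stages`, `seed`.
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    final_macro_f1 = x$stages$macro_f1[nrow(x$stages)],
    n_test = length(x$predictions),
    n_stages = nrow(x$stages),
    seed = x$seed
  )
}

#' @rdname tidy.pipeline_result
#' @param object A `pipeline_result`.
#' @return `autoplot()`: a ggplot bar chart of macro F1 by stage.
#' @export
autoplot.pipeline_result <- function(object, ...) {
  d <- object$stages %>%
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$macro_f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "macro F1", title = "Pipeline stage scores") +
    ggplot2::theme_minimal()
}

#' Tidy a feature-selection result
#'
#' @param x A `selection_result` from [greedy_wrapper()] /
#'   [select_features()].
#' @param ... Unused.
#' @return The wrapper audit tibble (`feature`, `accuracy`, `kept`).
#' @export
tidy.selection_result <- function(x, ...) x$audit

#' @rdname tidy.selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    n_candidates = nrow(x$audit),
    final_accuracy = max(x$audit$accuracy[x$audit$kept])
  )
}

#' @rdname tidy.selection_result
#' @param object A `selection_result`.
#' @return `autoplot()`: accuracy trajectory over the wrapper scan.
#' @export
autoplot.selection_result <- function(object, ...) {
  d <- object$audit %>% mutate(step = seq_len(n()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$accuracy,
                                  colour = .data$kept)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "candidate (MI order)", y = "validation accuracy",
                  colour = "kept") +
    ggplot2::theme_minimal()
}

#' Tidy an SSL result
#'
#' @param x An `ssl_result`.
#' @param ... Unused.
#' @return Per-round selected-instance counts by class.
#' @export
tidy.ssl_result <- function(x, ...) x$selected

#' @rdname tidy.ssl_result
#' @export
glance.ssl_result <- function(x, ...) {
  tibble::tibble(
    predicate = x$strategy$predicate, thr = x$strategy$thr,
    label_source = x$strategy$label_source,
    n_selected = x$n_selected, n_warnings = length(x$warnings)
  )
}

#' Plot chain structure of a re-ordering result
#'
#' @param object A `reorder_result`.
#' @param ... Unused.
#' @return A ggplot histogram of chain lengths.
#' @export
autoplot.reorder_result <- function(object, ...) {
  d <- tibble::tibble(length = lengths(object$chains))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey40") +
    ggplot2::labs(x = "chain length (windows)", y = "chains") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
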