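#' The eight locomotion and transportation activity classes
#'
#' The activity taxonomy used throughout the package: eight modes of
#' locomotion and transportation, coded 1 to 8. The classes split into a
#' *vehicle* subset (still, car, bus, train, subway), in which the body is
#' essentially static and the signal is dominated by vehicle vibration, and a
#' *dynamic* subset (walk, run, bike), dominated by periodic human movement.
#' The two subsets partition the class set.
#'
#' @return A tibble with columns `code` (integer 1-8), `name`, and `vehicle`
#'   (logical; `TRUE` for the vehicle/static subset).
#' @examples
#' activity_classes()
#' @export
activity_classes <- function() {
  tibble::tibble(
    code = 1:8,
    name = c("still", "walk", "run", "bike", "car", "bus", "train", "subway"),
    vehicle = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
}

#' @rdname activity_classes
#' @export
vehicle_codes <- function() activity_classes()$code[activity_classes()$vehicle]

#' @rdname activity_classes
#' @export
dynamic_codes <- function() activity_classes()$code[!activity_classes()$vehicle]

activity_names <- function() activity_classes()$name

check_labels <- function(labels, n_classes = 8L) {
  if (!all(labels %in% seq_len(n_classes))) {
    abort(sprintf("activity labels must be integers in 1..%d", n_classes))
  }
  invisible(as.integer(labels))
}
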