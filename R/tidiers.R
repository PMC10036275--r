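#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficient table of a scorch-height regression
#'
#' @param x A `scorch_regression`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.scorch_regression <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(co), estimate = co[, 1], std.error = co[, 2],
    statistic = co[, 3], p.value = co[, 4]
  )
}

#' One-row summary of a scorch-height regression
#'
#' @param x A `scorch_regression`.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `rmse`, `n`.
#' @export
glance.scorch_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, rmse = x$rmse, n = x$n)
}

#' Matched pairs of a detection report
#'
#' @param x A `match_report`.
#' @param ... Unused.
#' @return The pairs tibble (`segment_id`, `field_id`, `distance`).
#' @export
tidy.match_report <- function(x, ...) {
  if (is.null(x$pairs)) {
    tibble::tibble(segment_id = integer(0), field_id = integer(0),
                   distance = numeric(0))
  } else {
    x$pairs
  }
}

#' One-row summary of a detection report
#'
#' @param x A `match_report`.
#' @param ... Unused.
#' @return A one-row tibble: `tp`, `fn`, `fp`, `recall`, `precision`.
#' @export
glance.match_report <- function(x, ...) {
  tibble::tibble(tp = x$tp, fn = x$fn, fp = x$fp,
                 recall = x$recall, precision = x$precision)
}

#' One-row summary of a classification accuracy table
#'
#' @param x A `classification_summary`.
#' @param ... Unused.
#' @return A one-row tibble of counts and percent accuracies.
#' @export
glance.classification_summary <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_unburned = x$n_unburned, n_burned = x$n_burned,
    correct_unburned = x$correct_unburned, correct_burned = x$correct_burned,
    unburned_accuracy = x$unburned_accuracy,
    burned_accuracy = x$burned_accuracy,
    overall_accuracy = x$overall_accuracy
  )
}

#' Binned differences of a crown-volume-scorched agreement
#'
#' @param x A `cvs_agreement`.
#' @param ... Unused.
#' @return The bin tibble (`bin_center`, `count`).
#' @export
tidy.cvs_agreement <- function(x, ...) x$bins

#' One-row summary of a crown-volume-scorched agreement
#'
#' @param x A `cvs_agreement`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `within_10`, `within_30`.
#' @export
glance.cvs_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, within_10 = x$within_10, within_30 = x$within_30)
}
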