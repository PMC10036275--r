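#' Summarize burned/unburned classification against field labels
#'
#' Joins calls to field labels by `tree_id` and computes per-class and
#' overall accuracies (percent).
#'
#' @param burn_calls Tibble with `tree_id`, `label`.
#' @param field_labels Tibble with `tree_id`, `label` (field truth,
#'   `"burned"`/`"unburned"`).
#' @return A `classification_summary` object (list): counts per class,
#'   correct counts, `unburned_accuracy`, `burned_accuracy`,
#'   `overall_accuracy` (percent).
#' @export
summarize_classification <- function(burn_calls, field_labels) {
  j <- dplyr::inner_join(
    dplyr::select(burn_calls, "tree_id", call = "label"),
    dplyr::select(field_labels, "tree_id", truth = "label"),
    by = "tree_id"
  )
  missing_ids <- setdiff(burn_calls$tree_id, field_labels$tree_id)
  if (length(missing_ids)) {
    stop("no field label for tree id(s): ",
         paste(utils::head(missing_ids, 10), collapse = ", "), call. = FALSE)
  }
  j <- j[!is.na(j$call), ]
  n <- nrow(j)
  ub <- j$truth == "unburned"
  n_unburned <- sum(ub); n_burned <- sum(!ub)
  correct_unburned <- sum(ub & j$call == "unburned")
  correct_burned <- sum(!ub & j$call == "burned")
  structure(
    list(
      n = n, n_unburned = n_unburned, n_burned = n_burned,
      correct_unburned = correct_unburned, correct_burned = correct_burned,
      unburned_accuracy = 100 * correct_unburned / n_unburned,
      burned_accuracy = 100 * correct_burned / n_burned,
      overall_accuracy = 100 * (correct_unburned + correct_burned) / n
    ),
    class = "classification_summary"
  )
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf(
    "<classification_summary> n %d | unburned %.1f%% (%d/%d), burned %.1f%% (%d/%d), overall %.1f%%\n",
    x$n, x$unburned_accuracy, x$correct_unburned, x$n_unburned,
    x$burned_accuracy, x$correct_burned, x$n_burned, x$overall_accuracy))
  invisible(x)
}

#' Regression of observed on estimated scorch heights
#'
#' Ordinary least squares of the field-observed values on the estimates,
#' with the residual root-mean-square error.
#'
#' @param estimated,observed Paired numeric vectors (>= 3 pairs).
#' @return A `scorch_regression` object wrapping the [stats::lm()] fit,
#'   with `slope`, `intercept`, `r_squared`, `rmse`, `n`.
#' @export
scorch_height_regression <- function(estimated, observed) {
  if (length(estimated) != length(observed)) {
    stop("`estimated` and `observed` must be the same length", call. = FALSE)
  }
  ok <- is.finite(estimated) & is.finite(observed)
  estimated <- estimated[ok]; observed <- observed[ok]
  if (length(estimated) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(estimated) == 0) {
    stop("estimated values have zero variance", call. = FALSE)
  }
  fit <- stats::lm(observed ~ estimated)
  structure(
    list(fit = fit,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         rmse = sqrt(mean(stats::residuals(fit)^2)),
         n = length(estimated),
         data = tibble::tibble(estimated = estimated, observed = observed)),
    class = "scorch_regression"
  )
}

#' @export
print.scorch_regression <- function(x, ...) {
  cat(sprintf("<scorch_regression> n %d | slope %.2f, R^2 %.2f, RMSE %.2f m\n",
              x$n, x$slope, x$r_squared, x$rmse))
  invisible(x)
}

#' Agreement between estimated and observed crown volume scorched
#'
#' Signed differences (observed minus estimated, percent points) are binned
#' into 10-point bins centered on 0, and the fractions of trees within
#' +/-10 and +/-30 points are computed on the absolute difference
#' (thresholds inclusive).
#'
#' @param estimated,observed Paired percent values in \[0, 100\].
#' @return A `cvs_agreement` object: `differences`, binned counts tibble
#'   (`bin_center`, `count`), `within_10`, `within_30` (fractions), `n`.
#' @export
cvs_agreement <- function(estimated, observed) {
  ok <- is.finite(estimated) & is.finite(observed)
  d <- observed[ok] - estimated[ok]
  centers <- 10 * round(d / 10)
  bins <- tibble::tibble(bin_center = sort(unique(centers))) |>
    dplyr::mutate(count = vapply(.data$bin_center,
                                 function(b) sum(centers == b), numeric(1)))
  structure(
    list(differences = d, bins = bins,
         within_10 = mean(abs(d) <= 10),
         within_30 = mean(abs(d) <= 30),
         n = length(d)),
    class = "cvs_agreement"
  )
}

#' @export
print.cvs_agreement <- function(x, ...) {
  cat(sprintf("<cvs_agreement> n %d | %.1f%% within +/-10, %.1f%% within +/-30\n",
              x$n, 100 * x$within_10, 100 * x$within_30))
  invisible(x)
}

#' Round percentages for report display
#'
#' One decimal, half away from zero (so 92.05 prints as 92.1); raw values
#' are kept in all returned objects, this only formats.
#'
#' @param x Numeric vector of percentages.
#' @return Numeric vector rounded to one decimal.
#' @export
round_pct <- function(x) {
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}
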