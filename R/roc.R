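#' Empirical ROC curve from a per-threshold characteristics table
#'
#' Plots each threshold of a test as the point (1 - specificity,
#' sensitivity), anchors the curve at (0, 0) and (1, 1), and sorts by
#' false-alarm rate (hit rate as tie-break). Duplicate points are dropped.
#' The anchors make the area under the empirical polyline a proper
#' probability: without them a curve from a finite threshold set would not
#' span the unit square.
#'
#' @param chars A data frame with columns `sen` and `spe` (proportions),
#'   one row per threshold, e.g. from [accuracy_table()] or
#'   [halt_characteristics()]. If a `test` column is present and `test` is
#'   given, rows are filtered to that test first.
#' @param test Optional test identifier to filter on.
#' @return A tibble of class `roc_curve` with columns `fpr` and `tpr`,
#'   ordered from (0, 0) to (1, 1).
#' @examples
#' tab <- halt_characteristics("mainstudy")
#' curve <- roc_points(tab, test = "testA")
#' auc_trapezoid(curve)
#' @export
roc_points <- function(chars, test = NULL) {
  chars <- as_tibble(chars)
  if (!is.null(test) && "test" %in% names(chars)) {
    chars <- filter(chars, .data$test == !!test)
  }
  if (nrow(chars) == 0) stop_input("characteristics table is empty.")
  check_prob(chars$sen, "sen"); check_prob(chars$spe, "spe")
  pts <- tibble(fpr = c(0, 1 - chars$spe, 1), tpr = c(0, chars$sen, 1)) |>
    distinct() |>
    arrange(.data$fpr, .data$tpr)
  structure(pts, class = c("roc_curve", class(pts)))
}

#' Trapezoidal area under an ROC curve
#'
#' Integrates the ordered empirical points of a [roc_points()] curve by the
#' trapezoidal rule. The result is the probability that a randomly chosen
#' target-device / non-target-device pair is ordered correctly by the test.
#' No convex-hull or binormal smoothing is applied.
#'
#' @param curve An `roc_curve` (or any data frame with ordered `fpr`, `tpr`
#'   columns spanning (0,0) to (1,1)).
#' @return The AUC, a number in \[0, 1\].
#' @export
auc_trapezoid <- function(curve) {
  fpr <- curve$fpr; tpr <- curve$tpr
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @rdname roc_points
#' @param object An `roc_curve`.
#' @param ... Unused.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False-alarm rate (1 - specificity)",
      y = "Hit rate (sensitivity)",
      subtitle = sprintf("AUC = %.3f", auc_trapezoid(object))
    ) +
    ggplot2::theme_minimal()
}
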