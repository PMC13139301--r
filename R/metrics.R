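#' Regression metrics for paired observed / predicted affinities
#'
#' Computes the four standard CPI regression metrics on a paired vector of
#' observed affinities `y` and predictions `y_hat` of common length m:
#'
#' * MSE: mean squared error, `sum((y - y_hat)^2) / m`.
#' * CI: concordance index — over every ordered pair with `y_i > y_j`, the
#'   step score `h(y_hat_i - y_hat_j)` with `h(x) = 1` if `x > 0`, `0.5` if
#'   `x == 0`, `0` if `x < 0`, divided by the number Z of such pairs.
#' * R2: coefficient of determination,
#'   `1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`.
#' * PCC: Pearson correlation between `y` and `y_hat`.
#'
#' @param y observed affinities (length >= 2, finite, not all equal).
#' @param y_hat predicted affinities (same length, finite).
#' @return A `cpi_metrics` list with `mse`, `ci`, `r2`, `pcc`.
#' @examples
#' evaluate_predictions(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 3.7))
#' @export
evaluate_predictions <- function(y, y_hat) {
  if (length(y) != length(y_hat))
    stopf("length mismatch: y has %d entries, y_hat has %d",
          length(y), length(y_hat))
  m <- length(y)
  if (m < 2L) stopf("need at least 2 paired values")
  if (any(!is.finite(y)) || any(!is.finite(y_hat)))
    stopf("non-finite values in y or y_hat")
  sst <- sum((y - mean(y))^2)
  if (sst == 0)
    stopf("y is constant: CI, R2 and PCC are undefined")
  if (stats::sd(y_hat) == 0)
    stopf("y_hat is constant: PCC is undefined")
  mse <- sum((y - y_hat)^2) / m
  r2 <- 1 - sum((y - y_hat)^2) / sst
  pcc <- sum((y_hat - mean(y_hat)) * (y - mean(y))) /
    (sqrt(sum((y_hat - mean(y_hat))^2)) * sqrt(sum((y - mean(y))^2)))
  structure(list(mse = mse, ci = concordance_index(y, y_hat), r2 = r2,
                 pcc = pcc), class = "cpi_metrics")
}

#' Concordance index with half-credit for tied predictions
#'
#' @param y observed values; pairs are ordered by `y_i > y_j`.
#' @param y_hat predictions scored with the step function (ties score 0.5).
#' @return CI in \[0, 1\].
#' @export
concordance_index <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stopf("length mismatch in concordance_index")
  ord <- outer(y, y, ">")
  if (!any(ord)) stopf("all observed values tied: CI is undefined")
  d <- outer(y_hat, y_hat, "-")[ord]
  sum((d > 0) + 0.5 * (d == 0)) / sum(ord)
}

#' @export
print.cpi_metrics <- function(x, ...) {
  cat(sprintf("MSE %.4f | CI %.4f | R2 %.4f | PCC %.4f\n",
              x$mse, x$ci, x$r2, x$pcc))
  invisible(x)
}
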