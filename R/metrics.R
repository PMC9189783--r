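#' Model-comparison metric suite
#'
#' Computes the seven agreement metrics used to compare response models
#' against experimental data, all on the original response scale:
#' \describe{
#'   \item{r2}{\eqn{1 - SSE/SST}}
#'   \item{mse, rmse}{mean squared error and its square root}
#'   \item{mae}{mean absolute error}
#'   \item{aad}{\eqn{|\mathrm{mean}((y - y')/y')| \times 100} (percent)}
#'   \item{are}{\eqn{\mathrm{mean}(|y - y'|/y') \times 100} (percent)}
#'   \item{chi2}{Pearson's \eqn{\sum (y - y')^2 / y'} by default;
#'     `chi2_form = "relative"` gives \eqn{\sum ((y - y')/y')^2}}
#' }
#' Relative metrics require strictly positive predictions.
#'
#' @param y_exp observed responses.
#' @param y_pred model predictions (same length, positive where relative
#'   metrics are used).
#' @param chi2_form `"pearson"` (default) or `"relative"`.
#' @return A one-row data frame of class `metric_report` with columns
#'   `r2`, `mse`, `rmse`, `mae`, `aad`, `are`, `chi2`.
#' @examples
#' model_metrics(c(1, 2, 3), c(1, 1, 1))
#' @export
model_metrics <- function(y_exp, y_pred, chi2_form = c("pearson", "relative")) {
  chi2_form <- match.arg(chi2_form)
  y <- as.numeric(y_exp); yp <- as.numeric(y_pred)
  if (length(y) != length(yp))
    stop("observed and predicted vectors differ in length")
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations")
  if (any(yp == 0))
    stop("zero predicted values: relative metrics (AAD, ARE, chi2) undefined")
  err <- y - yp
  mse <- mean(err^2)
  out <- data.frame(
    r2 = 1 - sum(err^2) / sum((y - mean(y))^2),
    mse = mse,
    rmse = sqrt(mse),
    mae = mean(abs(err)),
    aad = abs(mean(err / yp)) * 100,
    are = mean(abs(err) / yp) * 100,
    chi2 = if (chi2_form == "pearson") sum(err^2 / yp) else sum((err / yp)^2)
  )
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Rank competing models metric by metric
#'
#' Given named metric reports, declares the winner of each metric (higher
#' is better for r2, lower for everything else) and an overall verdict by
#' majority over the metrics. Exact ties are flagged.
#'
#' @param reports named list of `metric_report` objects (>= 2).
#' @return A list with `per_metric` (data frame of metric, winner, values)
#'   and `overall` (the majority winner, or `"tie"`).
#' @examples
#' a <- model_metrics(c(1, 2, 3), c(1.1, 2.1, 2.9))
#' b <- model_metrics(c(1, 2, 3), c(1.4, 2.4, 2.6))
#' compare_models(list(good = a, bad = b))$overall
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2L || is.null(names(reports)))
    stop("supply a named list of at least two metric reports")
  metrics <- c("r2", "mse", "rmse", "mae", "aad", "are", "chi2")
  vals <- do.call(rbind, lapply(reports, function(r) unlist(r[metrics])))
  winner <- vapply(metrics, function(m) {
    v <- vals[, m]
    best <- if (m == "r2") max(v) else min(v)
    hits <- names(reports)[v == best]
    if (length(hits) > 1L) "tie" else hits
  }, character(1))
  per_metric <- data.frame(metric = metrics, winner = winner,
                           t(vals)[metrics, , drop = FALSE],
                           row.names = NULL, check.names = FALSE)
  tally <- table(winner[winner != "tie"])
  overall <- if (!length(tally)) "tie" else {
    top <- names(tally)[tally == max(tally)]
    if (length(top) > 1L) "tie" else top
  }
  list(per_metric = per_metric, overall = overall)
}
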