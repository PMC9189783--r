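#' Fit a first-order (screening) model on the coded scale
#'
#' Ordinary least squares of a response on the coded linear terms, with
#' optional two-factor interactions. On an orthogonal two-level design the
#' coefficients reduce to the usual contrasts \eqn{\sum z_i y / n}. A
#' factor is flagged significant when the t-test of its coefficient gives
#' p < `alpha`.
#'
#' @param design a `design_matrix` (or a coded matrix).
#' @param y numeric response, one value per run.
#' @param interactions include all two-factor interaction terms?
#' @param alpha significance cutoff for flagging factors (default 0.05).
#' @return An object of class `first_order_fit` with elements `b0`, `b`
#'   (named linear coefficients), `p_values`, `significant`, `sigma`,
#'   `residuals` and the underlying `lm` fit.
#' @examples
#' fs <- factor_set(c("a", "b"), c(0, 0), c(1, 1))
#' d <- two_level_factorial(fs)
#' y <- 3 + 2 * d$coded[, 1] - d$coded[, 2]
#' fit_first_order(d, y)$b  # c(a = 2, b = -1)
#' @export
fit_first_order <- function(design, y, interactions = FALSE, alpha = 0.05) {
  coded <- if (inherits(design, "design_matrix")) design$coded else design
  y <- as.numeric(y)
  if (length(y) != nrow(coded))
    stop("length(y) must equal the number of runs")
  df <- as.data.frame(coded)
  form <- if (interactions)
    stats::as.formula(paste("y ~ (", paste(colnames(coded), collapse = "+"), ")^2"))
  else
    stats::as.formula(paste("y ~", paste(colnames(coded), collapse = "+")))
  df$y <- y
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design: first-order model is not estimable")
  # noiseless screening data interpolate exactly; the "perfect fit"
  # warning from summary.lm is expected there, not actionable
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  lin <- colnames(coded)
  b <- stats::coef(fit)[lin]
  # saturated fits have no residual df; p-values are then undefined, not 0
  p <- if (fit$df.residual > 0) co[lin, "Pr(>|t|)"] else rep(NA_real_, length(lin))
  names(p) <- lin
  structure(
    list(
      b0 = unname(stats::coef(fit)[1L]),
      b = b,
      p_values = p,
      significant = !is.na(p) & p < alpha,
      sigma = sm$sigma,
      residuals = stats::residuals(fit),
      lm = fit
    ),
    class = "first_order_fit"
  )
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat("First-order fit: b0 =", format(x$b0), "\n")
  print(data.frame(coefficient = x$b, p = x$p_values,
                   significant = x$significant))
  invisible(x)
}

#' Path of steepest ascent from a first-order fit
#'
#' Steps the significant factors along the gradient of the fitted plane.
#' Step `j` moves factor `i` by `j * step_size * b_i / |b_ref|` coded
#' units, decoded to the actual scale; non-significant factors stay at
#' `base`. The reference factor defaults to the largest absolute
#' coefficient, so its coded increment per step equals `step_size`.
#'
#' @param fit a `first_order_fit`.
#' @param fs the [factor_set] the design was built from.
#' @param base actual levels of the starting point (usually the design
#'   center); vector of length k.
#' @param reference `"auto"` (largest `|b|` among significant factors) or
#'   a factor name.
#' @param step_size coded-unit step of the reference factor per candidate.
#' @param n_steps number of candidate points to emit.
#' @return A data frame with `step`, the actual levels of each candidate,
#'   and the fitted first-order prediction at each point (coded scale
#'   deltas are stored in attribute `"coded_delta"`).
#' @export
steepest_ascent_path <- function(fit, fs, base, reference = "auto",
                                 step_size = 1, n_steps = 10L) {
  stopifnot(inherits(fit, "first_order_fit"), inherits(fs, "factor_set"))
  b <- fit$b
  if (all(b == 0))
    stop("all first-order coefficients are zero; no ascent direction")
  sig <- fit$significant
  if (!any(sig))
    stop("no significant factor at the screening cutoff; ",
         "path of steepest ascent is undefined")
  if (identical(reference, "auto")) {
    cand <- names(b)[sig]
    reference <- cand[which.max(abs(b[cand]))]
  }
  if (!reference %in% names(b))
    stop("unknown reference factor: ", reference)
  b_ref <- abs(b[reference])
  dir <- ifelse(sig, b / b_ref, 0) # coded-unit move per unit step
  base <- as_level_matrix(base, fs, "'base'")
  base_coded <- code_levels(base, fs)
  steps <- seq_len(n_steps)
  coded <- base_coded[rep(1L, n_steps), , drop = FALSE] +
    outer(steps * step_size, dir)
  actual <- decode_levels(coded, fs)
  out <- data.frame(step = steps)
  out <- cbind(out, as.data.frame(actual))
  out$predicted <- as.numeric(fit$b0 + coded %*% b)
  attr(out, "coded_delta") <- outer(steps * step_size, dir)
  attr(out, "reference") <- reference
  out
}
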