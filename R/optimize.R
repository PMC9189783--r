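#' Larger-is-better desirability
#'
#' Linear one-sided desirability with weight 1: 0 at or below `L`, 1 at or
#' above the target `T`, linear in between.
#'
#' @param y response value(s).
#' @param L lower acceptability bound.
#' @param T target; must exceed `L`.
#' @return Desirability in [0, 1], vectorized over `y`.
#' @examples
#' desirability_maximize(c(0, 5, 10), L = 0, T = 10)
#' @export
desirability_maximize <- function(y, L, T) {
  if (!is.finite(L) || !is.finite(T) || T <= L)
    stop("target 'T' must exceed lower bound 'L'")
  pmin(1, pmax(0, (y - L) / (T - L)))
}

#' Locate the optimum of a fitted surface inside a coded box
#'
#' Coarse grid scan over the box followed (optionally) by a bounded
#' quasi-Newton polish from the best grid point. The default region is
#' the factorial cube [-1, +1]^k. Deterministic: no random restarts.
#'
#' @param fit a `surface_fit`.
#' @param lower,upper coded box bounds (scalars or length-k vectors).
#' @param grid_density grid points per dimension in the scan.
#' @param refine polish the best grid point with `optim(method =
#'   "L-BFGS-B")`?
#' @param fs optional [factor_set]; when given, the optimum is also
#'   reported on the actual scale.
#' @param desirability_limits optional `c(L, T)` used to score the
#'   optimum; defaults to the range of surface predictions over the grid.
#' @return A list of class `optimization_result`: `argmax` (coded),
#'   `argmax_actual` (or `NULL`), `predicted`, `desirability`, and a
#'   `trace` data frame of scan/polish stages.
#' @examples
#' opt <- optimize_surface(protease_surface())
#' opt$argmax  # all +1
#' @export
optimize_surface <- function(fit, lower = -1, upper = 1, grid_density = 5L,
                             refine = TRUE, fs = NULL,
                             desirability_limits = NULL) {
  stopifnot(inherits(fit, "surface_fit"))
  k <- fit$k
  lower <- rep_len(as.numeric(lower), k)
  upper <- rep_len(as.numeric(upper), k)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(upper <= lower))
    stop("bounds must be finite with upper > lower")
  grids <- mapply(function(lo, hi) seq(lo, hi, length.out = grid_density),
                  lower, upper, SIMPLIFY = FALSE)
  pts <- as.matrix(do.call(expand.grid, grids))
  colnames(pts) <- paste0("x", seq_len(k))
  vals <- predict(fit, pts)
  best <- which.max(vals)
  z <- pts[best, ]
  value <- vals[best]
  trace <- data.frame(stage = "grid", predicted = value)
  if (refine) {
    opt <- stats::optim(z, function(p) -predict(fit, p),
                        method = "L-BFGS-B", lower = lower, upper = upper)
    if (-opt$value >= value) {
      z <- opt$par
      value <- -opt$value
    }
    trace <- rbind(trace, data.frame(stage = "polish", predicted = value))
  }
  if (is.null(desirability_limits)) desirability_limits <- range(vals)
  d <- if (diff(desirability_limits) > 0)
    desirability_maximize(value, desirability_limits[1L],
                          desirability_limits[2L])
  else 1
  structure(
    list(argmax = z,
         argmax_actual = if (!is.null(fs)) drop(decode_levels(z, fs)) else NULL,
         predicted = value, desirability = d, trace = trace),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("Optimum (coded):", paste(format(x$argmax, digits = 4), collapse = ", "),
      "\npredicted response:", format(x$predicted, big.mark = ","),
      " desirability:", format(x$desirability, digits = 3), "\n")
  if (!is.null(x$argmax_actual))
    cat("actual levels:",
        paste(format(x$argmax_actual, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Confirmation-experiment validation rule
#'
#' A model-predicted optimum is ratified when the confirmation experiment
#' differs from the prediction by less than `threshold` percent:
#' `percent_difference = 100 * |observed - predicted| / predicted`.
#'
#' @param predicted model-predicted response at the optimum (> 0).
#' @param observed confirmed experimental response.
#' @param threshold acceptance threshold in percent (default 5).
#' @return A list of class `validation_verdict` with `predicted`,
#'   `observed`, `percent_difference` and logical `pass`.
#' @examples
#' validate_optimum(411713.87, 418763.45)  # 1.71%, pass
#' @export
validate_optimum <- function(predicted, observed, threshold = 5) {
  if (!is.finite(predicted) || predicted <= 0)
    stop("'predicted' must be a positive number")
  pd <- 100 * abs(observed - predicted) / predicted
  structure(list(predicted = predicted, observed = observed,
                 percent_difference = pd, threshold = threshold,
                 pass = pd < threshold),
            class = "validation_verdict")
}

#' @export
print.validation_verdict <- function(x, ...) {
  cat(sprintf("predicted %s, observed %s: %.2f%% difference -> %s (threshold %g%%)\n",
              format(x$predicted, big.mark = ","),
              format(x$observed, big.mark = ","),
              x$percent_difference,
              if (x$pass) "PASS" else "FAIL", x$threshold))
  invisible(x)
}
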