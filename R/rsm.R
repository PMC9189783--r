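quadratic_terms <- function(k, names = paste0("x", seq_len(k))) {
  pairs <- utils::combn(k, 2L)
  list(
    pairs = pairs,
    labels = c("(Intercept)", names,
               paste0(names[pairs[1L, ]], ":", names[pairs[2L, ]]),
               paste0(names, "^2"))
  )
}

quadratic_basis <- function(Z) {
  k <- ncol(Z)
  tm <- quadratic_terms(k, colnames(Z))
  inter <- apply(tm$pairs, 2L, function(p) Z[, p[1L]] * Z[, p[2L]])
  if (nrow(Z) == 1L) inter <- matrix(inter, nrow = 1L)
  X <- cbind(1, Z, inter, Z^2)
  colnames(X) <- tm$labels
  X
}

new_surface_fit <- function(beta, k, names, extras = list()) {
  out <- c(list(coefficients = beta, k = k, term_names = names), extras)
  class(out) <- "surface_fit"
  out
}

#' Fit the full second-order response surface
#'
#' Ordinary least squares of a response on the complete quadratic basis in
#' coded units: intercept, k linear, k(k-1)/2 two-factor interaction and k
#' pure quadratic terms (21 terms for k = 5). No term pruning is done: the
#' full model is always fitted.
#'
#' @param design a `design_matrix`, or a matrix of coded levels.
#' @param y numeric response, one value per run.
#' @return An object of class `surface_fit` with the coefficient vector,
#'   standard errors, `r2`, `adj_r2`, fitted values, residuals and (when a
#'   `design_matrix` was supplied) the design for downstream ANOVA.
#' @examples
#' d <- ccrd(protease_factors(), n_center = 8, alpha = 2)
#' y <- 10 + d$coded[, 1] + rnorm(nrow(d$coded), sd = 0.1)
#' fit <- fit_quadratic(d, y)
#' fit$r2
#' @export
fit_quadratic <- function(design, y) {
  coded <- if (inherits(design, "design_matrix")) design$coded else design
  y <- as.numeric(y)
  n <- nrow(coded)
  if (length(y) != n)
    stop("length(y) must equal the number of runs")
  X <- quadratic_basis(coded)
  p <- ncol(X)
  if (n <= p)
    stop("need more runs (", n, ") than model terms (", p, ")")
  qr_x <- qr(X)
  if (qr_x$rank < p)
    stop("singular quadratic basis: design does not support all ", p, " terms")
  beta <- qr.coef(qr_x, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  sigma2 <- sse / (n - p)
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(XtX_inv) * sigma2)
  names(se) <- names(beta)
  r2 <- 1 - sse / sst
  new_surface_fit(beta, ncol(coded), colnames(X), list(
    se = se,
    r2 = r2,
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p),
    sigma = sqrt(sigma2),
    fitted = fitted,
    residuals = res,
    y = y,
    design = if (inherits(design, "design_matrix")) design else NULL,
    coded = coded
  ))
}

#' Build a response surface from known coefficients
#'
#' Constructs a `surface_fit` directly from a 1 + 2k + k(k-1)/2 coefficient
#' vector in coded units (intercept, linear, interaction, quadratic order,
#' interactions in `combn(k, 2)` order). Used for published models and for
#' synthetic ground truths.
#'
#' @param beta numeric coefficient vector.
#' @param k number of factors.
#' @param factor_names optional factor names.
#' @return A `surface_fit` (without data-dependent statistics).
#' @examples
#' s <- surface_from_coefficients(c(1, 2, -1, 0, 0, 0), k = 2)
#' predict(s, c(1, 1))  # 1 + 2 - 1
#' @export
surface_from_coefficients <- function(beta, k,
                                      factor_names = paste0("x", seq_len(k))) {
  p <- 1 + 2 * k + k * (k - 1) / 2
  beta <- as.numeric(beta)
  if (length(beta) != p)
    stop("expected ", p, " coefficients for k = ", k, ", got ", length(beta))
  tm <- quadratic_terms(k, factor_names)
  names(beta) <- tm$labels
  new_surface_fit(beta, k, tm$labels)
}

#' The published second-order model for protease activity
#'
#' The 21-coefficient quadratic (coded units) reported for protease
#' activity (U) on the five-factor design of [protease_factors()]. Its
#' value at the coded origin is the constant term 312,416 U and its value
#' at the all-+1 corner, 411,713.7 U, is the study's predicted optimum.
#'
#' @return A `surface_fit`.
#' @examples
#' predict(protease_surface(), rep(1, 5))
#' @export
protease_surface <- function() {
  surface_from_coefficients(
    c(312416,
      34139.02, 8494.02, 3617.09, 6827.96, 3105.64,
      -4928.91, -1433.03, 12458.59, 6173.47, 437.72,
      4314.59, 6393.34, -2139.91, 1581.59, 442.72,
      10786.68, 1898.43, 178.84, 6132.32, 817.53),
    k = 5, factor_names = protease_factors()$name
  )
}

#' @export
predict.surface_fit <- function(object, newdata, ...) {
  Z <- newdata
  if (is.data.frame(Z)) Z <- as.matrix(Z)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  if (ncol(Z) != object$k)
    stop("points have ", ncol(Z), " columns; the surface has k = ", object$k)
  storage.mode(Z) <- "double"
  colnames(Z) <- paste0("x", seq_len(object$k))
  drop(quadratic_basis(Z) %*% object$coefficients)
}

#' @export
print.surface_fit <- function(x, ...) {
  cat("Second-order response surface in", x$k, "factors\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$r2))
    cat("r2 =", format(x$r2, digits = 4),
        " adjusted r2 =", format(x$adj_r2, digits = 4), "\n")
  invisible(x)
}

#' ANOVA with lack-of-fit decomposition for a fitted surface
#'
#' Decomposes the total sum of squares into model and residual, and the
#' residual into lack-of-fit and pure error using the replicate structure
#' of the design (runs sharing identical coded levels). The lack-of-fit F
#' statistic is MS_lof / MS_pe with (n_distinct - p, n - n_distinct)
#' degrees of freedom. Without replicated runs the lack-of-fit rows are
#' reported as `NA` (unavailable), never as zero.
#'
#' @param fit a `surface_fit` returned by [fit_quadratic()].
#' @return A data frame of class `surface_anova` with rows Model,
#'   Residual, `Lack of fit`, `Pure error` and Total, and columns `ss`,
#'   `df`, `ms`, `f` and `p`.
#' @export
surface_anova <- function(fit) {
  stopifnot(inherits(fit, "surface_fit"))
  if (is.null(fit$y))
    stop("this surface was built from coefficients only; ",
         "refit with fit_quadratic() to get an ANOVA")
  y <- fit$y
  n <- length(y)
  p <- length(fit$coefficients)
  grp <- replicate_groups(fit$coded)
  n_distinct <- length(unique(grp))
  sst <- sum((y - mean(y))^2)
  sse <- sum(fit$residuals^2)
  ssm <- sst - sse
  df_m <- p - 1L
  df_e <- n - p
  ms_m <- ssm / df_m
  ms_e <- sse / df_e
  f_m <- ms_m / ms_e
  p_m <- stats::pf(f_m, df_m, df_e, lower.tail = FALSE)
  has_rep <- n_distinct < n
  if (has_rep) {
    group_means <- ave(y, grp)
    ss_pe <- sum((y - group_means)^2)
    ss_lof <- sse - ss_pe
    df_pe <- n - n_distinct
    df_lof <- n_distinct - p
    ms_pe <- ss_pe / df_pe
    ms_lof <- ss_lof / df_lof
    f_lof <- if (ms_pe > 0) ms_lof / ms_pe else Inf
    p_lof <- if (df_lof > 0)
      stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
    else NA_real_
  } else {
    ss_pe <- ss_lof <- df_pe <- df_lof <- ms_pe <- ms_lof <-
      f_lof <- p_lof <- NA_real_
  }
  out <- data.frame(
    source = c("Model", "Residual", "Lack of fit", "Pure error", "Total"),
    ss = c(ssm, sse, ss_lof, ss_pe, sst),
    df = c(df_m, df_e, df_lof, df_pe, n - 1L),
    ms = c(ms_m, ms_e, ms_lof, ms_pe, NA),
    f = c(f_m, NA, f_lof, NA, NA),
    p = c(p_m, NA, p_lof, NA, NA)
  )
  class(out) <- c("surface_anova", "data.frame")
  out
}

#' @export
print.surface_anova <- function(x, ...) {
  printable <- x
  printable$ss <- signif(printable$ss, 6)
  printable$ms <- signif(printable$ms, 6)
  printable$f <- signif(printable$f, 4)
  printable$p <- signif(printable$p, 4)
  print.data.frame(printable, row.names = FALSE)
  invisible(x)
}
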