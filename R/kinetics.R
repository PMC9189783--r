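#' Logistic growth curve
#'
#' Sigmoid biomass model
#' \deqn{X(t) = \frac{X_0 X_{max} e^{\mu t}}{X_{max} - X_0 + X_0 e^{\mu t}}}
#' with initial biomass `x0`, carrying capacity `xmax` and maximum
#' specific growth rate `mu` (1/h). The curve starts at `x0`, saturates at
#' `xmax`, and has its inflection at `xmax / 2` where the slope equals
#' `mu * xmax / 4`.
#'
#' @param t time (h), vectorized.
#' @param x0,xmax,mu parameters; `0 < x0 < xmax`, `mu > 0`.
#' @return Biomass at `t`.
#' @examples
#' logistic_curve(0:10, x0 = 0.1, xmax = 5, mu = 0.8)
#' @export
logistic_curve <- function(t, x0, xmax, mu) {
  if (!is.finite(x0) || !is.finite(xmax) || !is.finite(mu) ||
      x0 <= 0 || xmax <= x0 || mu <= 0)
    stop("need 0 < x0 < xmax and mu > 0")
  # algebraically equal to x0*xmax*e^{mu t} / (xmax - x0 + x0 e^{mu t});
  # dividing through by e^{mu t} avoids overflow at large t
  xmax * x0 / (x0 + (xmax - x0) * exp(-mu * t))
}

#' Modified Gompertz accumulation curve
#'
#' Product/substrate sigmoid
#' \deqn{P(t) = P_{max} \exp\left(-\exp\left(\frac{r_{max} e}{P_{max}}
#'   (t_L - t) + 1\right)\right)}
#' parameterized by the asymptote `pmax`, the maximum volumetric rate
#' `rmax` (attained at the inflection) and the lag time `tlag` (where the
#' inflection tangent crosses zero).
#'
#' @param t time (h), vectorized.
#' @param pmax,rmax,tlag parameters; `pmax > 0`, `rmax > 0`, `tlag >= 0`.
#' @return Accumulated amount at `t`.
#' @examples
#' gompertz_curve(0:36, pmax = 7644.62, rmax = 315.46, tlag = 5.07)
#' @export
gompertz_curve <- function(t, pmax, rmax, tlag) {
  if (!is.finite(pmax) || !is.finite(rmax) || !is.finite(tlag) ||
      pmax <= 0 || rmax <= 0 || tlag < 0)
    stop("need pmax > 0, rmax > 0 and tlag >= 0")
  pmax * exp(-exp(rmax * exp(1) / pmax * (tlag - t) + 1))
}

kinetic_start <- function(t, y, model) {
  slope <- diff(y) / diff(t)
  i_max <- which.max(slope)
  s_max <- max(slope)
  if (model == "logistic") {
    pos <- y[y > 0]
    x0 <- if (length(pos)) max(min(pos), 1e-6) else 1e-6
    xmax <- max(y) * 1.05
    # in the exponential phase d log X / dt ~ mu
    ly <- log(pmax(y, x0 * 1e-3))
    mu <- max(diff(ly) / diff(t))
    mu <- if (is.finite(mu) && mu > 0) mu else 0.1
    list(x0 = x0, xmax = xmax, mu = mu)
  } else {
    pmax <- max(y) * 1.05
    rmax <- if (s_max > 0) s_max else 1e-3
    t_mid <- (t[i_max] + t[i_max + 1L]) / 2
    y_mid <- (y[i_max] + y[i_max + 1L]) / 2
    tlag <- max(0, t_mid - y_mid / rmax)
    list(pmax = pmax, rmax = rmax, tlag = tlag)
  }
}

#' Fit a sigmoid kinetic model to a fermentation time series
#'
#' Nonlinear least squares (Levenberg-Marquardt, via
#' \code{minpack.lm::nlsLM}) of the logistic or modified Gompertz model,
#' with data-driven starting values (initial/maximum observation, maximum
#' finite-difference slope, tangent-intercept lag) and positivity bounds.
#'
#' @param t times (h), strictly increasing, at least 5 points.
#' @param y non-negative measurements.
#' @param model `"logistic"` or `"gompertz"`.
#' @return An object of class `kinetic_fit`: named `parameters`, their
#'   standard errors, `fitted` values, and `stats` (adjusted r2, RMSE,
#'   MAE, and the F-test p-value against the constant model).
#' @examples
#' t <- seq(0, 36, 4)
#' y <- logistic_curve(t, 3.29, 482.46, 0.578)
#' fit_timeseries(t, y, "logistic")$parameters
#' @export
fit_timeseries <- function(t, y, model = c("logistic", "gompertz")) {
  model <- match.arg(model)
  t <- as.numeric(t); y <- as.numeric(y)
  if (length(t) < 5L) stop("need at least 5 time points")
  if (length(y) != length(t)) stop("t and y differ in length")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  if (any(y < 0)) stop("measurements must be non-negative")
  if (stats::sd(y) == 0)
    stop("constant series: kinetic parameters are not identifiable")
  start <- kinetic_start(t, y, model)
  df <- data.frame(t = t, y = y)
  big <- max(y) * 1e3 + 1
  if (model == "logistic") {
    form <- y ~ xmax * x0 / (x0 + (xmax - x0) * exp(-mu * t))
    lower <- c(x0 = 1e-9, xmax = 1e-9, mu = 1e-9)
    upper <- c(x0 = big, xmax = big, mu = 100)
  } else {
    form <- y ~ pmax * exp(-exp(rmax * exp(1) / pmax * (tlag - t) + 1))
    lower <- c(pmax = 1e-9, rmax = 1e-9, tlag = 0)
    upper <- c(pmax = big, rmax = big, tlag = max(t))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
    error = function(e)
      stop("kinetic fit (", model, ") did not converge: ",
           conditionMessage(e), "\nstart was: ",
           paste(names(start), signif(unlist(start), 4),
                 sep = "=", collapse = ", "))
  )
  est <- stats::coef(fit)
  fitted <- stats::fitted(fit)
  res <- y - fitted
  n <- length(y); p <- length(est)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  f <- ((sst - sse) / (p - 1)) / (sse / (n - p))
  stats <- c(
    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    rmse = sqrt(sse / n),
    mae = mean(abs(res)),
    p_value = stats::pf(f, p - 1, n - p, lower.tail = FALSE)
  )
  structure(
    list(model = model, parameters = est,
         se = summary(fit)$coefficients[, "Std. Error"],
         fitted = fitted, residuals = res, t = t, y = y,
         r2 = r2, stats = stats, nls = fit),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic fit:", x$model, "model\n")
  print(data.frame(estimate = x$parameters, se = x$se))
  cat("adj r2 =", format(x$stats["adj_r2"], digits = 4),
      " rmse =", format(x$stats["rmse"], digits = 4),
      " mae =", format(x$stats["mae"], digits = 4),
      " p =", format(x$stats["p_value"], digits = 3), "\n")
  invisible(x)
}

param_of <- function(x, name) {
  if (inherits(x, "kinetic_fit")) x$parameters[[name]]
  else x[[name]]
}

#' Yield and specific-rate coefficients from fitted kinetics
#'
#' Combines fitted biomass (logistic), product (Gompertz) and substrate
#' consumption (Gompertz) parameters into the standard coefficients:
#' \itemize{
#'   \item `yps`: product per substrate consumed, `Pmax / Smax` (mg/g);
#'   \item `yxs`: biomass per substrate, `(Xmax - X0) / Smax` (g/g);
#'   \item `ypx`: specific product yield, `Pmax` (converted to g) `/ Xmax`;
#'   \item `qp`, `qs`: specific rates `rmax / Xmax` of product formation
#'     and substrate consumption (per g DCW per h).
#' }
#'
#' @param biomass logistic `kinetic_fit` (or list with `x0`, `xmax`).
#' @param protein product Gompertz fit (or list with `pmax`, `rmax`);
#'   amounts in mg.
#' @param substrate substrate-consumption Gompertz fit (or list with
#'   `pmax`, `rmax`); amounts in g.
#' @param protein_unit unit of the product series, `"mg"` (converted to g
#'   for `ypx`) or `"g"`.
#' @return Named list `yps`, `yxs`, `ypx`, `qp`, `qs`.
#' @examples
#' derive_yields(list(x0 = 3.29, xmax = 482.46),
#'               list(pmax = 7644.62, rmax = 315.46),
#'               list(pmax = 7250.25, rmax = 397.64))
#' @export
derive_yields <- function(biomass, protein, substrate,
                          protein_unit = c("mg", "g")) {
  protein_unit <- match.arg(protein_unit)
  x0 <- param_of(biomass, "x0"); xmax <- param_of(biomass, "xmax")
  pmax <- param_of(protein, "pmax"); rp <- param_of(protein, "rmax")
  smax <- param_of(substrate, "pmax"); rs <- param_of(substrate, "rmax")
  if (is.null(x0) || is.null(xmax) || is.null(pmax) || is.null(smax))
    stop("missing kinetic parameters; supply fits or named lists")
  pmax_g <- if (protein_unit == "mg") pmax / 1000 else pmax
  list(
    yps = pmax / smax,
    yxs = (xmax - x0) / smax,
    ypx = pmax_g / xmax,
    qp = if (!is.null(rp)) rp / xmax else NA_real_,
    qs = if (!is.null(rs)) rs / xmax else NA_real_
  )
}
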