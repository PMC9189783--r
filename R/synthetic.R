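#' Ground truth for a simulated response surface
#'
#' Bundles the coefficient vector of a known quadratic surface with a
#' Gaussian noise level, for generating synthetic design-of-experiments
#' responses.
#'
#' @param surface a `surface_fit` (e.g. [surface_from_coefficients()] or
#'   [protease_surface()]).
#' @param noise_sd standard deviation of the additive Gaussian
#'   measurement noise, in response units.
#' @return A list of class `surface_truth`.
#' @export
surface_truth <- function(surface, noise_sd = 0) {
  stopifnot(inherits(surface, "surface_fit"))
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be non-negative")
  structure(list(surface = surface, noise_sd = noise_sd),
            class = "surface_truth")
}

#' Simulate responses over a design
#'
#' Evaluates the true quadratic at each coded design point and adds
#' seeded Gaussian noise. With `noise_sd = 0` the responses equal the
#' polynomial exactly; the same seed always reproduces the same table.
#'
#' @param truth a [surface_truth()].
#' @param design a `design_matrix` with matching k.
#' @param seed integer RNG seed.
#' @return A data frame with the actual levels, coded levels and the
#'   simulated `response` column.
#' @examples
#' d <- ccrd(protease_factors(), n_center = 8, alpha = 2)
#' sim <- simulate_doe(surface_truth(protease_surface(), 5000), d, seed = 1)
#' @export
simulate_doe <- function(truth, design, seed = 1L) {
  stopifnot(inherits(truth, "surface_truth"),
            inherits(design, "design_matrix"))
  if (ncol(design$coded) != truth$surface$k)
    stop("design has ", ncol(design$coded), " factors; truth expects ",
         truth$surface$k)
  mu <- predict(truth$surface, design$coded)
  y <- if (truth$noise_sd > 0)
    mu + with_seed(seed, stats::rnorm(length(mu), 0, truth$noise_sd))
  else mu
  out <- as.data.frame(design$actual)
  coded <- as.data.frame(design$coded)
  names(coded) <- paste0("z_", names(coded))
  cbind(run = seq_len(nrow(out)), out, coded,
        point_class = design$point_class, response = y)
}

#' Ground truth for simulated fermentation curves
#'
#' Logistic biomass dynamics plus modified Gompertz accumulation of total
#' protein, protease activity and consumed substrate, sampled at fixed
#' times with multiplicative Gaussian measurement noise (fermentation
#' assay error scales with signal).
#'
#' @param biomass list with `x0`, `xmax`, `mu` (g/L, g/L, 1/h).
#' @param protein,activity,substrate lists with `pmax`, `rmax`, `tlag`
#'   (mg / U / g basis as in the bundled study).
#' @param times sampling times (h), default 0-36 h every 4 h.
#' @param rel_sd relative standard deviation of the multiplicative noise.
#' @return A list of class `fermentation_truth`.
#' @export
fermentation_truth <- function(biomass, protein, activity, substrate,
                               times = seq(0, 36, by = 4), rel_sd = 0.01) {
  stopifnot(is.numeric(times), !is.unsorted(times, strictly = TRUE))
  if (!is.finite(rel_sd) || rel_sd < 0) stop("'rel_sd' must be non-negative")
  # validate parameter sets by evaluating each curve once
  logistic_curve(0, biomass$x0, biomass$xmax, biomass$mu)
  for (p in list(protein, activity, substrate))
    gompertz_curve(0, p$pmax, p$rmax, p$tlag)
  structure(list(biomass = biomass, protein = protein, activity = activity,
                 substrate = substrate, times = times, rel_sd = rel_sd),
            class = "fermentation_truth")
}

#' Fermentation truth preset: the bundled mutant strain
#'
#' The fitted bioreactor parameters of the improved (mutant) strain from
#' `fermopt_fixture("kinetic_params")`: logistic biomass (X0 = 3.29 g/L,
#' Xmax = 482.46 g/L, mu = 0.578 1/h) and Gompertz protein, activity and
#' substrate-consumption curves.
#'
#' @inheritParams fermentation_truth
#' @return A `fermentation_truth`.
#' @export
mutant_fermentation_truth <- function(times = seq(0, 36, by = 4),
                                      rel_sd = 0.01) {
  p <- fermopt_fixture("kinetic_params")
  p <- p[p$strain == "mutant", ]
  row <- function(series) p[p$series == series, ]
  b <- row("biomass")
  g <- function(series) {
    r <- row(series)
    list(pmax = r$pmax, rmax = r$rmax, tlag = r$tlag)
  }
  fermentation_truth(
    biomass = list(x0 = b$x0, xmax = b$xmax, mu = b$mu_max),
    protein = g("protein"), activity = g("activity"),
    substrate = g("substrate"), times = times, rel_sd = rel_sd
  )
}

#' Simulate a fermentation time series
#'
#' Each series equals its model curve times `(1 + N(0, rel_sd))`,
#' floored at zero; deterministic for a given seed.
#'
#' @param truth a [fermentation_truth()].
#' @param seed integer RNG seed.
#' @return A data frame with columns `time`, `biomass`, `protein`,
#'   `activity`, `substrate`.
#' @examples
#' sim <- simulate_fermentation(mutant_fermentation_truth(), seed = 1)
#' @export
simulate_fermentation <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "fermentation_truth"))
  t <- truth$times
  clean <- list(
    biomass = logistic_curve(t, truth$biomass$x0, truth$biomass$xmax,
                             truth$biomass$mu),
    protein = gompertz_curve(t, truth$protein$pmax, truth$protein$rmax,
                             truth$protein$tlag),
    activity = gompertz_curve(t, truth$activity$pmax, truth$activity$rmax,
                              truth$activity$tlag),
    substrate = gompertz_curve(t, truth$substrate$pmax, truth$substrate$rmax,
                               truth$substrate$tlag)
  )
  noisy <- if (truth$rel_sd > 0) {
    with_seed(seed, lapply(clean, function(v)
      pmax(0, v * (1 + stats::rnorm(length(v), 0, truth$rel_sd)))))
  } else clean
  data.frame(time = t, biomass = noisy$biomass, protein = noisy$protein,
             activity = noisy$activity, substrate = noisy$substrate)
}
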