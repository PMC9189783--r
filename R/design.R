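new_design_matrix <- function(coded, fs, point_class) {
  actual <- decode_levels(coded, fs)
  structure(
    list(
      coded = coded,
      actual = actual,
      point_class = factor(point_class,
                           levels = c("factorial", "axial", "center")),
      factors = fs
    ),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design with", nrow(x$coded), "runs in", nrow(x$factors), "factors (",
      paste(names(table(x$point_class)), table(x$point_class),
            sep = ": ", collapse = ", "), ")\n")
  df <- as.data.frame(x$coded)
  df$point_class <- x$point_class
  print(utils::head(df, 10L), ...)
  if (nrow(df) > 10L) cat("...", nrow(df) - 10L, "more runs\n")
  invisible(x)
}

#' @export
as.data.frame.design_matrix <- function(x, ..., coded = FALSE) {
  df <- as.data.frame(if (coded) x$coded else x$actual)
  df$point_class <- x$point_class
  df
}

#' Full two-level factorial design
#'
#' Generates the \eqn{2^k} factorial design in standard (Yates) order: the
#' first factor alternates fastest. Used to screen which medium components
#' have a significant first-order effect before any response-surface work.
#'
#' @param fs a [factor_set] with `k <= 12` factors.
#' @return A `design_matrix` whose coded rows are all +/-1 combinations.
#' @examples
#' d <- two_level_factorial(protease_factors())
#' nrow(d$coded)  # 32
#' @export
two_level_factorial <- function(fs) {
  stopifnot(inherits(fs, "factor_set"))
  k <- nrow(fs)
  if (k > 12L)
    stop("refusing to build a 2^", k, " factorial (k > 12)")
  coded <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  dimnames(coded) <- list(NULL, fs$name)
  new_design_matrix(coded, fs, rep("factorial", nrow(coded)))
}

#' Central composite rotatable design
#'
#' Builds the classical central composite design: the \eqn{2^k} factorial
#' cube, \eqn{2k} axial (star) points at coded distance `alpha`, and
#' `n_center` replicated center runs. Axial actual levels are
#' `center +/- alpha * half_range`. With `alpha = "rotatable"` the axial
#' distance is \eqn{F^{1/4}} where \eqn{F} is the number of factorial
#' points. The default `alpha = 2` reproduces the axial spacing of the
#' bundled five-factor protease design.
#'
#' @param fs a [factor_set].
#' @param n_center number of replicated center runs (>= 1).
#' @param alpha axial distance in coded units (> 1), or `"rotatable"`.
#' @return A `design_matrix` with factorial, axial and center rows, in
#'   that order.
#' @examples
#' d <- ccrd(protease_factors(), n_center = 8, alpha = 2)
#' table(d$point_class)  # 32 factorial, 10 axial, 8 center
#' @export
ccrd <- function(fs, n_center = 8L, alpha = 2) {
  stopifnot(inherits(fs, "factor_set"))
  k <- nrow(fs)
  n_center <- as.integer(n_center)
  if (n_center < 1L)
    stop("'n_center' must be at least 1")
  fact <- two_level_factorial(fs)$coded
  if (identical(alpha, "rotatable")) {
    alpha <- nrow(fact)^0.25
  } else {
    alpha <- as.numeric(alpha)
    if (!is.finite(alpha) || alpha <= 1)
      stop("'alpha' must exceed 1 (or be \"rotatable\")")
  }
  axial <- matrix(0, nrow = 2L * k, ncol = k, dimnames = list(NULL, fs$name))
  for (i in seq_len(k)) {
    axial[2L * i - 1L, i] <- -alpha
    axial[2L * i, i] <- alpha
  }
  center <- matrix(0, nrow = n_center, ncol = k,
                   dimnames = list(NULL, fs$name))
  coded <- rbind(fact, axial, center)
  cls <- c(rep("factorial", nrow(fact)), rep("axial", nrow(axial)),
           rep("center", n_center))
  out <- new_design_matrix(coded, fs, cls)
  attr(out, "alpha") <- alpha
  out
}

classify_coded_point <- function(z, tol = 1e-8) {
  nz <- abs(z) > tol
  if (!any(nz)) return("center")
  if (all(abs(abs(z) - 1) < tol)) return("factorial")
  if (sum(nz) == 1L) return("axial")
  "factorial" # off-grid points default to the cube class
}

#' Reconstruct a design object from actual factor levels
#'
#' Codes a table of actual levels against a factor set and classifies each
#' run as factorial, axial or center. This is how the bundled 50-run table
#' is turned back into a design for refitting.
#'
#' @param actual matrix or data frame of actual levels (one column per factor).
#' @param fs a [factor_set].
#' @param tol tolerance used when classifying coded levels.
#' @return A `design_matrix`.
#' @examples
#' runs <- fermopt_fixture("ccrd_runs")
#' d <- design_from_actual(runs[, 2:6], protease_factors())
#' table(d$point_class)
#' @export
design_from_actual <- function(actual, fs, tol = 1e-6) {
  coded <- code_levels(actual, fs)
  coded <- round(coded / tol) * tol # snap print-rounded levels to the grid
  cls <- apply(coded, 1L, classify_coded_point)
  new_design_matrix(coded, fs, cls)
}

#' Replicate groups of a design
#'
#' Runs with identical coded levels form replicate groups; within-group
#' spread is the pure-error component of the lack-of-fit ANOVA.
#'
#' @param design a `design_matrix`, or a numeric matrix of coded levels.
#' @param tol rounding tolerance when comparing rows.
#' @return Integer vector of group ids, one per run.
#' @export
replicate_groups <- function(design, tol = 1e-8) {
  coded <- if (inherits(design, "design_matrix")) design$coded else design
  key <- apply(round(coded / tol) * tol, 1L, paste, collapse = "\r")
  match(key, unique(key))
}
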