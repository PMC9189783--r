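#' Define a set of design factors
#'
#' A factor set holds, for each medium component (or other controllable
#' variable), the actual values assigned to the coded -1 and +1 levels.
#' The coded scale is the affine map that sends `low` to -1, `high` to +1
#' and their midpoint to 0; axial points of a central composite design sit
#' at `center +/- alpha * half_range` on the actual scale.
#'
#' @param name character vector of unique factor names.
#' @param low,high numeric vectors of actual values at the coded -1 and +1
#'   levels; `high` must exceed `low` elementwise.
#' @param units optional character vector of unit labels (recycled).
#' @return An object of class `factor_set`: a data frame with columns
#'   `name`, `low`, `high`, `units`, `center` and `half_range`.
#' @examples
#' factor_set(c("glucose", "yeast_extract"), low = c(5, 1), high = c(15, 3),
#'            units = c("g/L", "g/L"))
#' @export
factor_set <- function(name, low, high, units = "") {
  name <- as.character(name)
  k <- length(name)
  if (k < 2L)
    stop("a factor set needs at least 2 factors, got ", k)
  if (anyDuplicated(name))
    stop("factor names must be unique")
  low <- as.numeric(low)
  high <- as.numeric(high)
  if (length(low) != k || length(high) != k)
    stop("'low' and 'high' must match the number of factor names")
  if (any(!is.finite(low)) || any(!is.finite(high)))
    stop("factor levels must be finite")
  if (any(high <= low))
    stop("each 'high' level must exceed its 'low' level")
  fs <- data.frame(
    name = name,
    low = low,
    high = high,
    units = rep_len(as.character(units), k),
    center = (low + high) / 2,
    half_range = (high - low) / 2,
    stringsAsFactors = FALSE
  )
  class(fs) <- c("factor_set", "data.frame")
  fs
}

#' @export
print.factor_set <- function(x, ...) {
  cat("Factor set with", nrow(x), "factors\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' The five medium factors of the bundled protease study
#'
#' Cassava processing effluent (CPE, %), corn steep liquor (CSL, %),
#' casein (%), magnesium ions (g/L) and manganese ions (g/L), with the
#' factorial (-1/+1) levels used in the bundled 50-run central composite
#' design (`fermopt_fixture("ccrd_runs")`).
#'
#' @return A [factor_set] with five rows.
#' @examples
#' protease_factors()
#' @export
protease_factors <- function() {
  factor_set(
    name  = c("cpe", "csl", "casein", "mg", "mn"),
    low   = c(45.7, 23.2, 5.33, 0.16, 0.023),
    high  = c(48.1, 24.6, 6.93, 0.38, 0.039),
    units = c("%", "%", "%", "g/L", "g/L")
  )
}

as_level_matrix <- function(x, fs, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(fs))
    stop(what, " has ", ncol(x), " columns but the factor set has ",
         nrow(fs), " factors")
  storage.mode(x) <- "double"
  colnames(x) <- fs$name
  x
}

#' Convert actual factor levels to coded units (and back)
#'
#' `code_levels()` maps actual levels onto the coded scale where the
#' factorial low/high become -1/+1; `decode_levels()` is its inverse.
#' Both accept a vector (one point) or a matrix / data frame with one
#' column per factor.
#'
#' @param actual,coded numeric vector, matrix or data frame of levels.
#' @param fs a [factor_set].
#' @return A numeric matrix with one row per point and one column per factor.
#' @examples
#' fs <- protease_factors()
#' code_levels(c(46.9, 23.9, 6.13, 0.27, 0.031), fs)  # design center -> 0
#' decode_levels(rep(1, 5), fs)                       # +1 corner
#' @export
code_levels <- function(actual, fs) {
  a <- as_level_matrix(actual, fs, "'actual'")
  sweep(sweep(a, 2L, fs$center, "-"), 2L, fs$half_range, "/")
}

#' @rdname code_levels
#' @export
decode_levels <- function(coded, fs) {
  z <- as_level_matrix(coded, fs, "'coded'")
  sweep(sweep(z, 2L, fs$half_range, "*"), 2L, fs$center, "+")
}
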