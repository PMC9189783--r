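fixture_files <- c(
  screening = "screening.csv",
  ccrd_runs = "ccrd_runs.csv",
  kinetic_params = "kinetic_params.csv",
  atps_steps = "atps_steps.csv"
)

#' Bundled study tables
#'
#' Returns one of the plain-text tables shipped with the package, exactly
#' as published (thousands separators removed, nothing else altered):
#' \describe{
#'   \item{`screening`}{13 strain-screening records (clear-zone diameter,
#'     total protein, protease activity, with SDs; parent flagged).}
#'   \item{`ccrd_runs`}{the 50-run five-factor central composite design:
#'     actual factor levels, experimental total protein (mg) and protease
#'     activity (U), and the response-surface and neural-network
#'     predictions of both.}
#'   \item{`kinetic_params`}{fitted logistic / modified Gompertz
#'     parameters (with SEs), yield coefficients and goodness-of-fit for
#'     mutant and wild-type bioreactor runs.}
#'   \item{`atps_steps`}{aqueous two-phase purification steps (PEG
#'     molecular weight, total protein, total activity), crude extract
#'     first.}
#' }
#'
#' @param name one of `"screening"`, `"ccrd_runs"`, `"kinetic_params"`,
#'   `"atps_steps"`.
#' @return A data frame.
#' @examples
#' nrow(fermopt_fixture("ccrd_runs"))  # 50
#' @export
fermopt_fixture <- function(name) {
  if (length(name) != 1L || !name %in% names(fixture_files))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(names(fixture_files), collapse = ", "))
  path <- system.file("extdata", fixture_files[[name]], package = "fermopt",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and write run tables
#'
#' `read_runs()` reads a CSV of experimental runs and validates it
#' against a schema: every column in `factors` and `responses` must be
#' present and numeric, and the file must contain at least one run.
#' Errors name the offending column and row. `write_runs()` writes a run
#' table back to CSV at full double precision, so a write/read round trip
#' is lossless to 15 significant digits.
#'
#' @param path file path.
#' @param factors,responses character vectors of required column names.
#' @return `read_runs()`: a data frame of class `run_table`;
#'   `write_runs()`: the path, invisibly.
#' @export
read_runs <- function(path, factors, responses) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("could not parse ", path, ": ",
                                         conditionMessage(e)))
  if (nrow(d) == 0L) stop("empty run table: ", path)
  need <- c(factors, responses)
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  for (col in need) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column '", col, "', row ", bad[1L],
             ": \"", v[bad[1L]], "\"")
      d[[col]] <- num
    }
    if (any(!is.na(d[[col]]) & d[[col]] < 0) && col %in% responses)
      stop("negative response in column '", col, "', row ",
           which(d[[col]] < 0)[1L])
  }
  attr(d, "factors") <- factors
  attr(d, "responses") <- responses
  class(d) <- c("run_table", "data.frame")
  d
}

#' @param x a data frame of runs.
#' @rdname read_runs
#' @export
write_runs <- function(x, path) {
  out <- as.data.frame(x)
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- vapply(out[[col]], format, character(1), digits = 17)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
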