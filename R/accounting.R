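#' Percent improvement of a mutant over its parent
#'
#' `100 * (mutant - parent) / parent`, reported to `digits` decimal
#' places.
#'
#' @param mutant,parent activity (or other yield) values; `parent > 0`.
#' @param digits decimal places of the reported percentage.
#' @return Numeric percentage, vectorized over `mutant`.
#' @examples
#' improvement_percent(85873.38, 36209.54)  # 137.16
#' @export
improvement_percent <- function(mutant, parent, digits = 2L) {
  if (any(!is.finite(parent)) || any(parent <= 0))
    stop("'parent' must be positive")
  round(100 * (mutant - parent) / parent, digits)
}

#' Fold change
#'
#' Simple ratio `numerator / denominator`, reported to `digits` decimal
#' places, as used for activity-improvement folds.
#'
#' @param numerator,denominator values; `denominator > 0`.
#' @param digits decimal places.
#' @return Numeric fold, vectorized.
#' @examples
#' fold_change(85873.38, 36209.54)  # 2.37
#' @export
fold_change <- function(numerator, denominator, digits = 2L) {
  if (any(!is.finite(denominator)) || any(denominator <= 0))
    stop("'denominator' must be positive")
  round(numerator / denominator, digits)
}

#' Strain-screening improvement table
#'
#' Adds the percent-improvement column to a screening table (one row per
#' strain with total protein and activity means), computed against the
#' row flagged as the parent.
#'
#' @param records data frame with at least `code`, `activity_u` and a
#'   logical `is_parent` column (as returned by
#'   `fermopt_fixture("screening")`).
#' @return The table with an `improvement_pct` column (`NA` for the
#'   parent row).
#' @examples
#' screening_report(fermopt_fixture("screening"))
#' @export
screening_report <- function(records) {
  need <- c("code", "activity_u", "is_parent")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("screening table lacks column(s): ", paste(missing, collapse = ", "))
  if (sum(records$is_parent) != 1L)
    stop("exactly one record must be flagged as the parent")
  parent <- records$activity_u[records$is_parent]
  if (parent <= 0) stop("parent activity must be positive")
  records$improvement_pct <-
    ifelse(records$is_parent, NA_real_,
           improvement_percent(records$activity_u, parent))
  records
}

#' Purification accounting across process steps
#'
#' For each step, specific activity = activity / protein (U/mg), yield =
#' 100 * activity / crude activity (%), and purification fold = specific
#' activity / crude specific activity. The crude extract itself reports
#' 100% yield and fold 1 by construction.
#'
#' @param steps data frame with columns `label`, `protein_mg`,
#'   `activity_u` (one row per purification step).
#' @param crude single-row data frame (same columns) for the crude
#'   extract; defaults to the row of `steps` labelled `"crude"`.
#' @return A data frame of class `purification_report` with
#'   `specific_activity`, `yield_pct` and `fold` columns, crude row first.
#' @examples
#' purification_report(fermopt_fixture("atps_steps"))
#' @export
purification_report <- function(steps, crude = NULL) {
  need <- c("label", "protein_mg", "activity_u")
  missing <- setdiff(need, names(steps))
  if (length(missing))
    stop("purification table lacks column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(crude)) {
    is_crude <- steps$label == "crude"
    if (sum(is_crude) != 1L)
      stop("no single row labelled 'crude'; pass the crude step explicitly")
    crude <- steps[is_crude, ]
    steps <- steps[!is_crude, ]
  }
  all_rows <- rbind(crude, steps)
  if (any(all_rows$protein_mg <= 0))
    stop("total protein must be positive in every step")
  if (any(all_rows$activity_u <= 0))
    stop("total activity must be positive in every step")
  crude_specific <- crude$activity_u / crude$protein_mg
  all_rows$specific_activity <- all_rows$activity_u / all_rows$protein_mg
  all_rows$yield_pct <- 100 * all_rows$activity_u / crude$activity_u
  all_rows$fold <- all_rows$specific_activity / crude_specific
  rownames(all_rows) <- NULL
  class(all_rows) <- c("purification_report", "data.frame")
  all_rows
}

#' Phase-partition statistics of a two-phase system
#'
#' Volume ratio `Vr = V_top / V_bottom` and partition coefficient
#' `K = C_top / C_bottom` of an aqueous two-phase system. When all enzyme
#' reports to the top phase (`c_bottom = 0`), `K` is infinite and the
#' system is flagged as one-sided.
#'
#' @param v_top,v_bottom phase volumes (mL), both > 0.
#' @param c_top,c_bottom enzyme concentrations (U/mL), non-negative.
#' @return List with `volume_ratio`, `partition_coefficient` and logical
#'   `one_sided`.
#' @examples
#' partition_stats(6, 4, 300, 100)  # Vr 1.5, K 3
#' @export
partition_stats <- function(v_top, v_bottom, c_top, c_bottom) {
  if (!is.finite(v_top) || !is.finite(v_bottom) ||
      v_top <= 0 || v_bottom <= 0)
    stop("phase volumes must be positive")
  if (c_top < 0 || c_bottom < 0)
    stop("concentrations must be non-negative")
  one_sided <- c_bottom == 0
  list(
    volume_ratio = v_top / v_bottom,
    partition_coefficient = if (one_sided) Inf else c_top / c_bottom,
    one_sided = one_sided
  )
}
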