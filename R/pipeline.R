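# Stage activities reported for the screening -> factorial -> ascent
# sequence of the bundled study; inputs to the fold arithmetic.
study_stage_activities <- function() {
  c(parent = 36209.54, mutant = 85873.38,
    factorial = 188956.23, ascent = 306945.52)
}

#' Reproduce the bundled optimization study end to end
#'
#' Runs the whole analysis on the packaged tables: strain-screening
#' improvement arithmetic, the second-order response-surface refit with
#' lack-of-fit ANOVA, a seeded neural-network fit, the seven-metric
#' model comparison, the desirability optimum of the published surface
#' with its confirmation verdict, kinetic yield coefficients, and the
#' two-phase purification report. Rerunning with the same seed gives an
#' identical report.
#'
#' @param ann_seed seed for the network split and weight initialization.
#' @param out_dir optional directory; when given, the report is also
#'   written there as `report.json`.
#' @return A nested list (class `fermopt_report`) with one element per
#'   stage plus `seeds` and `package_version`.
#' @examples
#' \donttest{
#' rep <- reproduce_study(ann_seed = 7)
#' rep$rsm$r2
#' rep$optimum$validation$percent_difference
#' }
#' @export
reproduce_study <- function(ann_seed = 7L, out_dir = NULL) {
  fs <- protease_factors()
  runs <- fermopt_fixture("ccrd_runs")

  scr <- screening_report(fermopt_fixture("screening"))
  stage <- study_stage_activities()
  screening <- list(
    table = scr,
    best_mutant = scr$code[which.max(scr$improvement_pct)],
    best_improvement_pct = max(scr$improvement_pct, na.rm = TRUE),
    fold_mutation = fold_change(stage[["mutant"]], stage[["parent"]]),
    fold_factorial = fold_change(stage[["factorial"]], stage[["mutant"]]),
    fold_overall = fold_change(stage[["ascent"]], stage[["parent"]])
  )

  design <- design_from_actual(runs[, c("cpe", "csl", "casein", "mg", "mn")], fs)
  rsm_fit <- fit_quadratic(design, runs$activity_exp)
  rsm <- list(coefficients = rsm_fit$coefficients, r2 = rsm_fit$r2,
              adj_r2 = rsm_fit$adj_r2, anova = surface_anova(rsm_fit))

  spec <- ann_spec(n_inputs = 5L, n_hidden = 12L, seed = ann_seed)
  net <- train_ann(as.matrix(runs[, c("cpe", "csl", "casein", "mg", "mn")]),
                   runs$activity_exp, spec)
  ann <- list(performance = net$performance,
              overall_r2 = net$performance["overall", "r2"],
              split_sizes = lengths(net$split), stopped = net$stopped)

  metrics <- list(
    activity = compare_models(list(
      rsm = model_metrics(runs$activity_exp, runs$activity_rsm),
      ann = model_metrics(runs$activity_exp, runs$activity_ann))),
    protein = compare_models(list(
      rsm = model_metrics(runs$protein_exp, runs$protein_rsm),
      ann = model_metrics(runs$protein_exp, runs$protein_ann)))
  )

  opt <- optimize_surface(protease_surface(), fs = fs)
  optimum <- list(argmax = opt$argmax, argmax_actual = opt$argmax_actual,
                  predicted = opt$predicted,
                  validation = validate_optimum(opt$predicted, 418763.45))

  kp <- fermopt_fixture("kinetic_params")
  mk <- kp[kp$strain == "mutant", ]
  pick <- function(s) mk[mk$series == s, ]
  kinetics <- list(
    parameters = mk,
    yields = derive_yields(
      list(x0 = pick("biomass")$x0, xmax = pick("biomass")$xmax),
      list(pmax = pick("protein")$pmax, rmax = pick("protein")$rmax),
      list(pmax = pick("substrate")$pmax, rmax = pick("substrate")$rmax))
  )

  purification <- purification_report(fermopt_fixture("atps_steps"))

  report <- structure(
    list(screening = screening, rsm = rsm, ann = ann, metrics = metrics,
         optimum = optimum, kinetics = kinetics, purification = purification,
         seeds = c(ann = ann_seed),
         package_version = as.character(utils::packageVersion("fermopt"))),
    class = "fermopt_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_to_json <- function(report) {
  rapply(unclass(report), function(x) {
    if (inherits(x, "data.frame")) as.list(x) else x
  }, how = "replace", classes = c("data.frame", "numeric", "character",
                                  "integer", "logical"))
}

#' Run the analysis pipeline from a configuration
#'
#' Executes any subset of the pipeline stages on user data. `config` is a
#' named list; a stage runs when its entry is present. Supported stages:
#' \describe{
#'   \item{screening}{`list(table = <data frame or CSV path>)`}
#'   \item{rsm}{`list(runs =, factors =, response =)` where `factors` is
#'     a [factor_set] and `response` names a column of `runs`.}
#'   \item{ann}{as rsm, plus optional `n_hidden` and `seed`.}
#'   \item{kinetics}{`list(data =, series = c(biomass = "logistic", ...))`
#'     where `data` has a `time` column.}
#'   \item{purification}{`list(steps = <data frame or CSV path>)`}
#' }
#' An empty config returns an empty report; a stage with missing inputs
#' aborts with an error naming the stage.
#'
#' @param config named list of stage configurations.
#' @return A list with one element per executed stage, plus `seeds`.
#' @export
run_pipeline <- function(config = list()) {
  known <- c("screening", "rsm", "ann", "kinetics", "purification")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown pipeline stage(s): ", paste(extra, collapse = ", "))
  report <- list()
  seeds <- c()
  get_table <- function(x, stage, what) {
    if (is.null(x))
      stop("stage '", stage, "': missing input '", what, "'")
    if (is.character(x)) {
      if (!file.exists(x))
        stop("stage '", stage, "': input file not found: ", x)
      utils::read.csv(x, stringsAsFactors = FALSE)
    } else as.data.frame(x)
  }
  if (!is.null(config$screening)) {
    tab <- get_table(config$screening$table, "screening", "table")
    report$screening <- screening_report(tab)
  }
  for (stage in intersect(c("rsm", "ann"), names(config))) {
    cfg <- config[[stage]]
    runs <- get_table(cfg$runs, stage, "runs")
    fs <- cfg$factors
    if (is.null(fs) || !inherits(fs, "factor_set"))
      stop("stage '", stage, "': 'factors' must be a factor_set")
    if (is.null(cfg$response) || !cfg$response %in% names(runs))
      stop("stage '", stage, "': response column not found in runs")
    X <- runs[, fs$name, drop = FALSE]
    y <- runs[[cfg$response]]
    if (stage == "rsm") {
      fit <- fit_quadratic(design_from_actual(X, fs), y)
      report$rsm <- list(coefficients = fit$coefficients, r2 = fit$r2,
                         anova = surface_anova(fit))
    } else {
      seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
      seeds["ann"] <- seed
      spec <- ann_spec(n_inputs = nrow(fs),
                       n_hidden = if (is.null(cfg$n_hidden)) 12L
                                  else cfg$n_hidden,
                       seed = seed)
      net <- train_ann(as.matrix(X), y, spec)
      report$ann <- list(performance = net$performance,
                         stopped = net$stopped)
    }
  }
  if (!is.null(config$kinetics)) {
    cfg <- config$kinetics
    dat <- get_table(cfg$data, "kinetics", "data")
    if (!"time" %in% names(dat))
      stop("stage 'kinetics': data needs a 'time' column")
    series <- cfg$series
    if (is.null(series))
      stop("stage 'kinetics': missing input 'series'")
    bad <- setdiff(names(series), names(dat))
    if (length(bad))
      stop("stage 'kinetics': series column(s) not in data: ",
           paste(bad, collapse = ", "))
    report$kinetics <- lapply(stats::setNames(names(series), names(series)),
                              function(s)
                                fit_timeseries(dat$time, dat[[s]],
                                               model = series[[s]]))
  }
  if (!is.null(config$purification)) {
    steps <- get_table(config$purification$steps, "purification", "steps")
    report$purification <- purification_report(steps)
  }
  report$seeds <- seeds
  report
}
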