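#' Summarise final-step performance across runs
#'
#' Produces the Base/New/Overall summary table: for each mode (named element
#' of `ledgers`), the mean and standard deviation over runs of the final
#' evaluated step's macro-F1 per split.
#'
#' @param ledgers a named list of [metrics_ledger()]s (names = modes), or a
#'   single ledger.
#' @return a tidy data.frame with columns `mode`, `split`, `mean`, `sd`,
#'   `n_runs`.
#' @export
summarize_runs <- function(ledgers) {
  if (inherits(ledgers, "metrics_ledger")) ledgers <- list(run = ledgers)
  stopifnot(length(ledgers) >= 1L)
  out <- do.call(rbind, lapply(names(ledgers), function(mode) {
    finals <- final_summaries(ledgers[[mode]])
    agg <- stats::aggregate(f1 ~ split, finals,
                            function(v) c(mean = mean(v), sd = stats::sd(v),
                                          n = length(v)))
    data.frame(mode = mode, split = agg$split,
               mean = agg$f1[, "mean"],
               sd = ifelse(is.na(agg$f1[, "sd"]), 0, agg$f1[, "sd"]),
               n_runs = as.integer(agg$f1[, "n"]))
  }))
  rownames(out) <- NULL
  out
}

#' Final-step summary rows of a ledger
#'
#' @param ledger a [metrics_ledger()].
#' @return data.frame with one row per run and split at that run's last
#'   evaluated step.
#' @export
final_summaries <- function(ledger) {
  s <- ledger$summary_history
  do.call(rbind, lapply(split(s, s$run), function(d) {
    d[d$step == max(d$step), , drop = FALSE]
  }))
}

#' Aggregate a parameter sweep into tidy long format
#'
#' @param results a named list: `results[[param_value]]` is the
#'   [metrics_ledger()] of the run at that parameter value; `NULL` elements
#'   (failed or missing grid cells) produce explicit `NA` rows rather than
#'   silent omission.
#' @param param name of the swept parameter (e.g. `"margin"`, `"alpha"`).
#' @return data.frame with columns `param`, `value`, `split`, `mean`, `sd`,
#'   `n_runs`.
#' @export
sweep_report <- function(results, param) {
  stopifnot(is.list(results), length(results) > 0L, !is.null(names(results)))
  out <- do.call(rbind, lapply(names(results), function(v) {
    led <- results[[v]]
    if (is.null(led))
      return(data.frame(param = param, value = as.numeric(v),
                        split = NA_character_, mean = NA_real_, sd = NA_real_,
                        n_runs = 0L))
    s <- summarize_runs(list(x = led))
    data.frame(param = param, value = as.numeric(v), split = s$split,
               mean = s$mean, sd = s$sd, n_runs = s$n_runs)
  }))
  rownames(out) <- NULL
  out
}

#' Run a one-parameter sweep
#'
#' Re-runs an experiment across a grid of margins or refresh ratios (the two
#' sensitivity analyses the framework exposes), holding everything else
#' fixed.
#'
#' @param config a [run_config()].
#' @param data experiment data (see [run_experiment()]).
#' @param param `"margin"` or `"alpha"`.
#' @param values numeric grid, e.g. `c(0.2, 1, 2, 3)` for the margin or
#'   `seq(0, 1, 0.2)` for the refresh ratio.
#' @return the [sweep_report()] data.frame; the per-value ledgers are
#'   attached as the `"ledgers"` attribute.
#' @export
run_sweep <- function(config, data, param = c("margin", "alpha"), values) {
  param <- match.arg(param)
  results <- lapply(values, function(v) {
    cfg <- config
    if (param == "margin") cfg$loss$margin <- v else cfg$alpha <- v
    run_experiment(cfg, data)
  })
  names(results) <- values
  rep_ <- sweep_report(results, param)
  attr(rep_, "ledgers") <- results
  rep_
}

#' Write run artifacts to disk
#'
#' Persists the per-step tidy metrics as CSV and the final summary as JSON.
#'
#' @param ledger a [metrics_ledger()].
#' @param dir output directory (created if needed).
#' @param mode mode label used in the summary.
#' @return invisibly, the paths written.
#' @export
write_run_artifacts <- function(ledger, dir, mode = "full") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  steps_csv <- file.path(dir, "step_metrics.csv")
  utils::write.csv(ledger$summary_history, steps_csv, row.names = FALSE)
  class_csv <- file.path(dir, "class_metrics.csv")
  utils::write.csv(ledger$class_history, class_csv, row.names = FALSE)
  summary_json <- file.path(dir, "summary.json")
  s <- summarize_runs(stats::setNames(list(ledger), mode))
  jsonlite::write_json(s, summary_json, dataframe = "rows", digits = NA)
  invisible(c(steps_csv, class_csv, summary_json))
}
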