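#' Per-trial metrics for a whole trial set
#'
#' Applies [sway_metrics()] to every trial; trials whose metrics cannot be
#' computed are reported with a warning and dropped rather than aborting
#' the batch.
#'
#' @param trials a [trial_set] or list of [cop_trial] objects.
#' @param ... passed to [sway_metrics()].
#' @return data.frame, one row per successfully processed trial.
#' @export
metrics_table <- function(trials, ...) {
  if (inherits(trials, "trial_set")) trials <- trials$trials
  rows <- list()
  for (i in seq_along(trials)) {
    row <- tryCatch(sway_metrics(trials[[i]], ...), error = function(e) {
      tr <- trials[[i]]
      warning(sprintf("metrics failed for %s/%s/s%d: %s", tr$subject_id,
                      tr$condition, tr$session, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no trial produced metrics")
  do.call(rbind, rows)
}

#' Render a reliability table in the conventional report layout
#'
#' One Markdown table per condition: rows are variable x group, columns the
#' session summaries `mean +/- SD (SE)`, ICC and its 95% CI, and the SEM.
#' Metrics and ICC are rounded to 2 decimals (CSV outputs keep full
#' precision).
#'
#' @param rel data.frame from [reliability_table()].
#' @param condition condition to render.
#' @return character vector of Markdown lines.
#' @export
render_condition_table <- function(rel, condition) {
  rc <- rel[rel$condition == condition, , drop = FALSE]
  disp <- stats::setNames(sway_variable_names(TRUE), sway_variable_names())
  lines <- c(
    sprintf("### Condition %s", condition),
    "",
    "| Variable | Group | 1st measurement | 2nd measurement | ICC | 95% CI | SEM |",
    "|---|---|---|---|---|---|---|")
  fmt <- function(m, s, se) sprintf("%.2f ± %.2f (%.2f)", m, s, se)
  for (v in intersect(names(disp), unique(rc$variable))) {
    for (grp in unique(rc$group)) {
      r <- rc[rc$variable == v & rc$group == grp, , drop = FALSE]
      if (!nrow(r)) next
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %s | %.2f | %.2f–%.2f | %.2f |",
        disp[[v]], grp, fmt(r$mean1, r$sd1, r$se1), fmt(r$mean2, r$sd2, r$se2),
        r$icc, r$ci_low, r$ci_high, r$sem_measurement))
    }
  }
  c(lines, "")
}

#' Run the full stabilometric pipeline
#'
#' Reads trials from a manifest or synthesizes a cohort, computes the
#' twelve per-trial variables, assembles test-retest reliability tables per
#' condition and a cohort summary (group descriptives and Romberg
#' quotients), and writes everything under `out_dir`:
#' `metrics.csv`, `reliability.csv`, `report.md`, `romberg.csv`,
#' `run_config.json` (the exact configuration used), `ground_truth.csv`
#' (synthetic runs only) and `run.log`.
#'
#' @param out_dir output directory (created if missing).
#' @param manifest path to a trial manifest CSV (see [read_manifest()]);
#'   mutually exclusive with `synthetic`.
#' @param synthetic a [synthetic_config()]; used when no manifest is given
#'   (defaults apply when both are `NULL`).
#' @param alpha CI level for the reliability tables.
#' @param rq_pair condition pair for the Romberg quotient (eyes open, eyes
#'   closed).
#' @param log_transform compute the reliability tables on log-metrics.
#' @param ... metric options passed to [sway_metrics()] via
#'   [metrics_table()].
#' @return invisibly, a list with `metrics`, `reliability`, `romberg` and
#'   the output paths.
#' @export
run_pipeline <- function(out_dir, manifest = NULL, synthetic = NULL,
                         alpha = 0.05, rq_pair = c("FO", "FC"),
                         log_transform = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("stabilometry %s",
                         as.character(utils::packageVersion("stabilometry"))),
                 sprintf("R %s", getRversion()))
  truth <- NULL
  if (!is.null(manifest)) {
    withCallingHandlers(
      trials <- read_manifest(manifest),
      warning = function(w) {
        log_lines <<- c(log_lines, paste("WARN:", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    log_lines <- c(log_lines, sprintf("input: manifest %s (%d trials)",
                                      manifest, length(trials)))
  } else {
    if (is.null(synthetic)) synthetic <- synthetic_config()
    cohort <- generate_cohort(synthetic)
    trials <- cohort$trials
    truth <- cohort$truth
    log_lines <- c(log_lines, sprintf(
      "input: synthetic cohort, seed %d, designed ICC %.4f (%d trials)",
      synthetic$seed, synthetic$designed_icc, length(trials)))
  }
  withCallingHandlers(
    metrics <- metrics_table(trials, ...),
    warning = function(w) {
      log_lines <<- c(log_lines, paste("WARN:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  withCallingHandlers(
    rel <- reliability_table(metrics, alpha = alpha,
                             log_transform = log_transform),
    warning = function(w) {
      log_lines <<- c(log_lines, paste("WARN:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  rq <- romberg_table(metrics, pair = rq_pair)

  paths <- list(metrics = file.path(out_dir, "metrics.csv"),
                reliability = file.path(out_dir, "reliability.csv"),
                romberg = file.path(out_dir, "romberg.csv"),
                report = file.path(out_dir, "report.md"),
                config = file.path(out_dir, "run_config.json"),
                log = file.path(out_dir, "run.log"))
  utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  utils::write.csv(rel, paths$reliability, row.names = FALSE)
  utils::write.csv(rq, paths$romberg, row.names = FALSE)
  if (!is.null(truth)) {
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }

  report <- c("# Stabilometric test-retest reliability report", "",
              sprintf("%d trials, %d reliability cells.",
                      nrow(metrics), nrow(rel)), "",
              "## Cohort summary", "",
              "| Group | Subjects | Romberg quotient |", "|---|---|---|")
  for (grp in unique(metrics$group)) {
    rqg <- rq[rq$group == grp, , drop = FALSE]
    report <- c(report, sprintf(
      "| %s | %d | %s |", grp,
      length(unique(metrics$subject_id[metrics$group == grp])),
      paste(sprintf("%s %.2f ± %.2f", rqg$variable, rqg$mean_rq,
                    rqg$sd_rq), collapse = "; ")))
  }
  report <- c(report, "")
  for (cond in unique(rel$condition)) {
    report <- c(report, render_condition_table(rel, cond))
  }
  writeLines(report, paths$report)

  cfg <- if (!is.null(manifest)) {
    list(mode = "manifest", manifest = manifest, alpha = alpha,
         rq_pair = rq_pair, log_transform = log_transform)
  } else {
    c(list(mode = "synthetic", alpha = alpha, rq_pair = rq_pair,
           log_transform = log_transform), unclass(synthetic))
  }
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA)
  writeLines(c(log_lines, sprintf("wrote %d metric rows, %d reliability rows",
                                  nrow(metrics), nrow(rel))), paths$log)
  invisible(list(metrics = metrics, reliability = rel, romberg = rq,
                 truth = truth, paths = paths))
}
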