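#' Run the full conditioning battery over multiple seeds
#'
#' Runs every applicable (task, mode) pair of the battery for each seed and
#' aggregates trials-to-criterion with the median and interquartile range.
#' Fully deterministic given the seed list.
#'
#' @param config A [learning_config()].
#' @param modes Character vector of systems to run.
#' @param seeds Integer vector of model-initialization seeds.
#' @param battery A list of [task_spec()]s, as from [task_battery()].
#' @param keep_curves Whether to retain the full per-trial learning curves
#'   (memory-heavy for many seeds; medians do not need them).
#' @return A list of class `"battery_report"` with `runs` (one row per
#'   task/phase/mode/seed), `summary` (median and IQR per task/phase/mode),
#'   `curves`, `config`, and `seeds`.
#' @examples
#' \donttest{
#' rep <- run_battery(seeds = 1, modes = "intact",
#'                    battery = task_battery()["a_minus"])
#' rep$summary
#' }
#' @export
run_battery <- function(config = learning_config(),
                        modes = c("intact", "lesioned"),
                        seeds = 1:25,
                        battery = task_battery(),
                        keep_curves = FALSE) {
  stopifnot(length(seeds) >= 1L)
  modes <- match.arg(modes, several.ok = TRUE)
  rows <- list()
  curves <- list()
  for (task in battery) {
    for (mode in intersect(task$modes, modes)) {
      for (seed in seeds) {
        res <- run_task(task, mode, config, seed)
        rows[[length(rows) + 1L]] <- data.frame(
          task = task$name, phase = res$phases_run, mode = mode,
          seed = as.integer(seed), trials = res$per_phase_trials,
          converged = res$per_phase_converged, stringsAsFactors = FALSE)
        if (keep_curves) {
          curves[[paste(task$name, mode, seed, sep = ".")]] <- res$curves
        }
      }
    }
  }
  runs <- do.call(rbind, rows)
  rownames(runs) <- NULL
  structure(list(runs = runs, summary = summarize_runs(runs),
                 curves = curves, config = config,
                 seeds = as.integer(seeds)),
            class = "battery_report")
}

summarize_runs <- function(runs) {
  key <- interaction(runs$task, runs$phase, runs$mode, drop = TRUE)
  parts <- split(runs, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    q <- stats::quantile(d$trials, c(0.25, 0.75), names = FALSE, type = 7)
    data.frame(task = d$task[1], phase = d$phase[1], mode = d$mode[1],
               median_trials = stats::median(d$trials),
               iqr_low = q[1], iqr_high = q[2],
               n_seeds = nrow(d),
               prop_converged = mean(d$converged),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$task, out$phase, out$mode), ]
  rownames(out) <- NULL
  out
}

#' @export
print.battery_report <- function(x, ...) {
  cat(sprintf("<battery_report> %d runs, %d seeds\n",
              nrow(x$runs), length(x$seeds)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export a battery report to CSV and JSON
#'
#' Writes `runs.csv` (one row per task/phase/mode/seed), `summary.csv`
#' (medians), `config.json`, and `curves.json` (full CR series, when the
#' report retained them) under `dir`. [read_report()] round-trips the runs
#' and summary losslessly.
#'
#' @param report A [run_battery()] report.
#' @param dir Output directory, created if needed.
#' @return The directory path, invisibly.
#' @export
export_report <- function(report, dir) {
  stopifnot(inherits(report, "battery_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$config[setdiff(names(report$config), NULL)],
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(
    lapply(report$curves, function(phases)
      lapply(phases, function(cv) as.list(cv))),
    file.path(dir, "curves.json"), digits = NA)
  invisible(dir)
}

#' Read back an exported battery report
#'
#' @param dir Directory written by [export_report()].
#' @return A `battery_report` (curves restored when present).
#' @export
read_report <- function(dir) {
  runs <- utils::read.csv(file.path(dir, "runs.csv"), stringsAsFactors = FALSE)
  curves_path <- file.path(dir, "curves.json")
  curves <- if (file.exists(curves_path)) {
    lapply(jsonlite::read_json(curves_path), function(phases)
      lapply(phases, function(ph)
        data.frame(trial = unlist(ph$trial), cue = unlist(ph$cue),
                   cr = unlist(ph$cr), us = unlist(ph$us),
                   stringsAsFactors = FALSE)))
  } else {
    list()
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  structure(list(runs = runs, summary = summarize_runs(runs),
                 curves = curves,
                 config = do.call(learning_config,
                                  cfg[names(cfg) %in% names(formals(learning_config))]),
                 seeds = sort(unique(runs$seed))),
            class = "battery_report")
}

#' Plot per-phase learning curves
#'
#' One panel per phase, CR against trial with one line per cue type,
#' rendered with base graphics to a PNG file.
#'
#' @param result A [run_task()] result with at least one curve.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return The path, invisibly.
#' @export
plot_curves <- function(result, path, width = 720, height = 300) {
  stopifnot(inherits(result, "run_result"))
  if (length(result$curves) == 0L) {
    stop("result contains no learning curves", call. = FALSE)
  }
  grDevices::png(path, width = width, height = height * length(result$curves))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(result$curves), 1), mar = c(4, 4, 2, 1))
  for (i in seq_along(result$curves)) {
    cv <- result$curves[[i]]
    cues <- unique(cv$cue)
    graphics::plot(NULL, xlim = c(1, max(cv$trial)), ylim = c(0, 1),
                   xlab = "trial", ylab = "CR",
                   main = sprintf("%s (%s) - phase %d", result$task,
                                  result$mode, result$phases_run[i]))
    for (k in seq_along(cues)) {
      d <- cv[cv$cue == cues[k], ]
      graphics::lines(d$trial, d$cr, col = k, lwd = 2)
    }
    graphics::legend("right", legend = cues, col = seq_along(cues),
                     lwd = 2, bty = "n")
  }
  invisible(path)
}

#' Reference trials-to-criterion counts
#'
#' The per-task/phase/mode trial counts reported for the reference
#' implementation of this architecture, shipped as a plain-text table and
#' used only for side-by-side comparison.
#'
#' @return A data frame with columns `task`, `phase`, `mode`,
#'   `reference_trials`.
#' @export
reference_counts <- function() {
  utils::read.csv(system.file("extdata", "reference_trial_counts.csv",
                              package = "qinncond"),
                  stringsAsFactors = FALSE)
}

#' Compare a battery report with the reference counts
#'
#' Merges the report's median trials-to-criterion with [reference_counts()]
#' and adds absolute and relative deviations. Reference rows missing from
#' the report are kept with `NA` medians and flagged, never dropped.
#'
#' @param report A [run_battery()] report.
#' @return A data frame with one row per reference (task, phase, mode).
#' @export
compare_to_reference <- function(report) {
  stopifnot(inherits(report, "battery_report"))
  ref <- reference_counts()
  out <- merge(ref, report$summary[, c("task", "phase", "mode",
                                       "median_trials", "n_seeds")],
               by = c("task", "phase", "mode"), all.x = TRUE)
  out$abs_deviation <- out$median_trials - out$reference_trials
  out$rel_deviation <- out$abs_deviation / out$reference_trials
  out$missing <- is.na(out$median_trials)
  out[order(out$task, out$phase, out$mode), ]
}
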