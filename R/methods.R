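# S3 methods for run results.

#' @export
print.pa_run <- function(x, ...) {
  cat(sprintf("Scenario run %s: %d agents, %d weekdays x %d replicates (seed %s)\n",
              x$scenario, nrow(x$agents), x$days, x$reps,
              format(x$seed)))
  cat(sprintf("  population mean daily MVPA: %.1f min\n",
              mean(x$rep_mean_daily)))
  cat(sprintf("  probability clamping events: %d\n", x$clamp_count))
  cat("  use mvpa_summary(), correlate() or plot() for details\n")
  invisible(x)
}

#' @export
summary.pa_run <- function(object, guideline = 60, ...) {
  mvpa_summary(object, guideline = guideline)
}

#' Histogram of per-agent mean daily MVPA
#'
#' @param x `pa_run`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.pa_run <- function(x, ...) {
  y <- rowMeans(x$rep_mean_daily)
  graphics::hist(y, breaks = 30, col = "grey80", border = "white",
                 main = sprintf("Scenario %s", x$scenario),
                 xlab = "mean daily MVPA (min)", ...)
  graphics::abline(v = mean(y), lty = 2)
  invisible(x)
}

#' Export a run result as a CSV bundle with a JSON manifest
#'
#' Writes per-agent outcomes (`agents.csv`: covariates, mean daily MVPA,
#' walking/outdoor/sport minutes), the population MVPA-by-type matrix
#' (`type_mvpa.csv`) and a `manifest.json` with the scenario, seed and
#' protocol.
#'
#' @param run `pa_run`.
#' @param dir output directory.
#' @return invisible vector of written paths.
#' @export
write_run_csv <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ag <- run$agents
  ag$mean_mvpa <- rowMeans(run$rep_mean_daily)
  ag$walk_min <- rowMeans(run$walk_min)
  ag$outdoor_min <- rowMeans(run$outdoor_min)
  ag$fsa_min <- rowMeans(run$fsa_min)
  p1 <- file.path(dir, "agents.csv")
  write.csv(ag, p1, row.names = FALSE)
  p2 <- file.path(dir, "type_mvpa.csv")
  write.csv(data.frame(type = rownames(run$type_mvpa), run$type_mvpa),
            p2, row.names = FALSE)
  p3 <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(scenario = run$scenario, seed = run$seed,
                            days = run$days, reps = run$reps,
                            n_agents = nrow(ag)),
                       p3, auto_unbox = TRUE)
  invisible(c(p1, p2, p3))
}
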