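# Outcome surface: population means, guideline shares, MVPA composition by
# activity type, SEP breakdown, attribute correlations, distribution
# comparison and the peer-influence sensitivity sweeps.

#' Summarise a scenario run
#'
#' Population mean daily MVPA minutes with a 95% t-interval over replicate
#' means, the percentage of agents whose average stays below the guideline
#' (60 min/day), the percentage meeting the guideline on every simulated
#' weekday, the percentage of total population MVPA by activity type, and
#' mean daily MVPA by SEP band.
#'
#' @param run `pa_run` from [run_experiment()].
#' @param guideline threshold in min/day (60).
#' @return object of class `pa_summary`.
#' @export
mvpa_summary <- function(run, guideline = 60) {
  reps <- run$reps
  rep_pop_mean <- colMeans(run$rep_mean_daily)
  ci <- function(x) {
    if (length(x) < 2) return(0)
    qt(0.975, length(x) - 1) * sd(x) / sqrt(length(x))
  }
  rep_below <- vapply(seq_len(reps), function(r) {
    100 * mean(run$rep_mean_daily[, r] < guideline)
  }, 0)
  rep_always <- vapply(seq_len(reps), function(r) {
    100 * mean(apply(run$daily[, , r, drop = FALSE] >= guideline, 1, all))
  }, 0)
  tot <- rowSums(run$type_mvpa)
  share <- 100 * tot / sum(tot)
  sep_means <- vapply(SEP_LEVELS, function(lv) {
    sel <- run$agents$sep == lv
    if (!any(sel)) return(NA_real_)
    mean(colMeans(run$rep_mean_daily[sel, , drop = FALSE]))
  }, 0)
  structure(list(
    scenario = run$scenario, reps = reps, days = run$days,
    n_agents = nrow(run$agents),
    mean_mvpa = mean(rep_pop_mean), ci95 = ci(rep_pop_mean),
    pct_below = mean(rep_below), pct_below_ci95 = ci(rep_below),
    pct_always = mean(rep_always),
    share_by_type = share, mean_by_sep = sep_means,
    guideline = guideline), class = "pa_summary")
}

#' @export
print.pa_summary <- function(x, ...) {
  cat(sprintf("Scenario %s: %d agents, %d weekdays x %d replicates\n",
              x$scenario, x$n_agents, x$days, x$reps))
  cat(sprintf("  mean daily MVPA: %.1f min (95%% CI +/- %.1f)\n",
              x$mean_mvpa, x$ci95))
  cat(sprintf("  agents below %d min/day on average: %.1f%%; meeting it every day: %.1f%%\n",
              x$guideline, x$pct_below, x$pct_always))
  top <- sort(x$share_by_type[x$share_by_type > 0], decreasing = TRUE)
  cat("  MVPA by activity:",
      paste(sprintf("%s %.0f%%", names(top), top), collapse = ", "), "\n")
  cat("  mean by SEP:",
      paste(sprintf("%s %.1f", names(x$mean_by_sep), x$mean_by_sep),
            collapse = ", "), "\n")
  invisible(x)
}

#' Correlate agents' mean daily MVPA with their attributes
#'
#' Pearson correlations of per-agent mean daily MVPA minutes against the
#' activity tendency A, outdoor preference O, mean daily walking minutes,
#' number of weekly sport sessions, mean daily outdoor-play minutes, the
#' deprivation quintile (1 = least deprived) and household cars. A
#' zero-variance attribute yields `NA`, not 0.
#'
#' @param run `pa_run`.
#' @return data.frame with columns `attribute` and `r`.
#' @export
correlate <- function(run) {
  y <- rowMeans(run$rep_mean_daily)
  covs <- list(
    A = run$agents$A, O = run$agents$O,
    walking_time = rowMeans(run$walk_min),
    fsa_count = run$agents$fsa_count,
    outdoor_time = rowMeans(run$outdoor_min),
    simd = run$agents$simd_quintile,
    n_cars = run$agents$n_cars)
  r <- vapply(covs, function(v) {
    if (sd(v) == 0 || sd(y) == 0) NA_real_ else cor(y, v)
  }, 0)
  data.frame(attribute = names(covs), r = unname(r),
             stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Standard two-sample KS statistic (maximum ECDF gap) and asymptotic
#' p-value, used to compare simulated MVPA distributions with empirical ones.
#'
#' @param sample_a,sample_b numeric vectors of daily MVPA minutes.
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  kt <- suppressWarnings(ks.test(sample_a, sample_b))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Sensitivity sweep over the peer-influence parameters
#'
#' For `delta` (friend adjustment of the activity tendency, range 0-1) the
#' reported outcome is the percentage of agents whose mean MVPA stays below
#' `low_threshold` (50 min/day); for `lambda` (presence feedback on outdoor
#' play, range 0-0.6) it is the population mean MVPA. Values share a root
#' seed (paired comparison) and, within a scenario, a single attempt-rate
#' calibration performed with `lambda = 0`.
#'
#' @param env,pop environment and population.
#' @param param `"delta"` or `"lambda"`.
#' @param values numeric vector of parameter values.
#' @param scenarios scenario ids (default `"S1"`).
#' @param days,reps protocol per point.
#' @param seed root seed.
#' @param base_params baseline `pa_params`.
#' @param low_threshold threshold for the delta outcome (50).
#' @return data.frame with one row per (scenario, value): `mean_mvpa`,
#'   `pct_below_low`, and `outcome` (the sweep's headline measure).
#' @export
sweep_interactions <- function(env, pop, param = c("delta", "lambda"),
                               values, scenarios = "S1", days = 10,
                               reps = 3, seed = 1,
                               base_params = sim_params(),
                               low_threshold = 50) {
  force(env); force(pop)
  param <- match.arg(param)
  out <- list()
  for (sc in scenarios) {
    sc_params <- apply_scenario(base_params, sc)
    set.seed(derive_seed(seed, 100))
    ctx <- precompute_context(env, pop, sc_params)
    rates <- calibrate_attempt_rates(ctx, seed)
    for (v in values) {
      p <- unclass(sc_params)
      p[[param]] <- v
      class(p) <- "pa_params"
      run <- run_experiment(env, pop, sc = NULL, days = days, reps = reps,
                            seed = seed, base_params = p,
                            attempt_rates = rates)
      mm <- mean(colMeans(run$rep_mean_daily))
      pb <- 100 * mean(rowMeans(run$rep_mean_daily) < low_threshold)
      out[[length(out) + 1]] <- data.frame(
        scenario = sc, param = param, value = v, mean_mvpa = mm,
        pct_below_low = pb,
        outcome = if (param == "delta") pb else mm)
    }
  }
  do.call(rbind, out)
}
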