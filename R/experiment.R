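# Experiment protocol: replicate runs over simulated weekdays, the
# frequency-to-attempt calibration dry pass, and the grid calibration of
# weekly activity frequencies against a time-use target.

#' Calibrate per-attempt trigger probabilities
#'
#' The behavioural frequencies `F_neigh` and `F_shop` are weekday-scale
#' probabilities, but the spontaneous selection procedure fires roughly 4
#' attempts per idle hour. This dry pass runs the full engine for a few days
#' with presence feedback disabled (`lambda = 0`, so the feedback is never
#' absorbed into the calibration) and applies a multiplicative fixed-point
#' update to the per-attempt probabilities until the realised population
#' episode rates match the configured frequencies (scaled by the population
#' mean of `O * s` for neighbourhood play, which enters the decision
#' multiplicatively). The friend-meeting initiation probability is calibrated
#' the same way, compensating for the scheduling conflicts that would
#' otherwise deflate realised hosted meetings below `F_friend`.
#'
#' @param ctx context from [precompute_context()].
#' @param seed integer seed.
#' @param days dry-pass weekdays per iteration (default 6).
#' @param iters fixed-point iterations (default 4); the converged later
#'   iterations are averaged geometrically.
#' @return list with `q_neigh`, `q_shop` and `q_friend`.
#' @export
calibrate_attempt_rates <- function(ctx, seed = 1, days = 6, iters = 4) {
  force(ctx)
  dry <- ctx
  dry$params$lambda <- 0
  target_neigh <- ctx$params$F_neigh * mean(ctx$O * ctx$s)
  target_shop <- ctx$params$F_shop
  target_friend <- ctx$params$F_friend
  qhat <- list(neigh = numeric(0), shop = numeric(0), friend = numeric(0))
  for (it in seq_len(iters)) {
    if (target_neigh <= 0 && target_shop <= 0 && target_friend <= 0) break
    set.seed(derive_seed(seed, 300 + it))
    ep <- c(play = 0, shop = 0)
    hosted <- 0
    for (d in seq_len(days)) {
      ev <- run_day_ctx(dry, weekday = (d - 1L) %% 5L + 1L)
      ep <- ep + attr(ev, "episodes")
      hosted <- hosted + attr(ev, "meetings_hosted")
    }
    rate <- c(neigh = ep[["play"]], shop = ep[["shop"]],
              friend = hosted) / (ctx$n * days)
    upd <- function(q, target, r) {
      if (target <= 0) return(0)
      if (r <= 0) return(min(q * 3, 1))
      clamp(q * clamp(target / r, 0.2, 5), 0, 1)
    }
    dry$q_neigh <- upd(dry$q_neigh, target_neigh, rate[["neigh"]])
    dry$q_shop <- upd(dry$q_shop, target_shop, rate[["shop"]])
    dry$q_friend <- upd(dry$q_friend, target_friend, rate[["friend"]])
    if (it >= 3) {
      # near the fixed point each one-step update is itself an estimate of
      # the fixed point; averaging the converged ones (the first two
      # iterations are transient) shrinks the Monte-Carlo error of the
      # delivered rate with the square root of the pooled dry days
      qhat$neigh <- c(qhat$neigh, dry$q_neigh)
      qhat$shop <- c(qhat$shop, dry$q_shop)
      qhat$friend <- c(qhat$friend, dry$q_friend)
    }
  }
  avg <- function(v, q_last, target) {
    if (target <= 0) return(0)
    v <- v[v > 0]
    if (length(v) == 0) return(q_last)
    clamp(exp(mean(log(v))), 0, 1)
  }
  list(q_neigh = avg(qhat$neigh, dry$q_neigh, target_neigh),
       q_shop = avg(qhat$shop, dry$q_shop, target_shop),
       q_friend = avg(qhat$friend, dry$q_friend, target_friend))
}

#' Run a scenario experiment
#'
#' Applies the scenario to the baseline parameters, precomputes the context,
#' calibrates the per-attempt probabilities, and simulates `reps` independent
#' replicates of `days` weekdays each (days cycle Monday-Friday). Results are
#' bit-reproducible for a fixed seed; replicates use derived sub-seeds.
#'
#' @param env `pa_environment`.
#' @param pop `pa_population`.
#' @param sc scenario id (`"S1"`..`"S8"`), `pa_scenario`, or NULL to use
#'   `base_params` as-is.
#' @param days weekdays per replicate (default 30).
#' @param reps replicates (default 10).
#' @param seed integer root seed.
#' @param base_params baseline `pa_params`.
#' @param attempt_rates optional precomputed [calibrate_attempt_rates()]
#'   output (reused across paired runs of a sensitivity sweep).
#' @param keep_events if TRUE the full event logs are retained (memory-heavy;
#'   used by audits).
#' @param calib_days,calib_iters dry-pass controls.
#' @return object of class `pa_run`; see [mvpa_summary()] and [correlate()].
#' @export
run_experiment <- function(env, pop, sc = "S1", days = 30, reps = 10,
                           seed = 1, base_params = sim_params(),
                           attempt_rates = NULL, keep_events = FALSE,
                           calib_days = 6, calib_iters = 4) {
  force(env); force(pop)      # arguments may carry RNG-consuming promises
  params <- if (is.null(sc)) base_params else apply_scenario(base_params, sc)
  sc_id <- attr(params, "scenario") %||% "custom"
  set.seed(derive_seed(seed, 100))
  ctx <- precompute_context(env, pop, params)
  if (is.null(attempt_rates)) {
    attempt_rates <- calibrate_attempt_rates(ctx, seed, days = calib_days,
                                             iters = calib_iters)
  }
  ctx$q_neigh <- attempt_rates$q_neigh
  ctx$q_shop <- attempt_rates$q_shop
  ctx$q_friend <- attempt_rates$q_friend %||% params$F_friend

  n <- ctx$n
  ntype <- length(ACT_TYPES)
  daily <- array(0, dim = c(n, days, reps))
  type_mvpa <- matrix(0, ntype, reps, dimnames = list(ACT_TYPES, NULL))
  walk_min <- outdoor_min <- fsa_min <- matrix(0, n, reps)
  as_min <- meet_min <- neigh_min <- matrix(0, n, reps)
  clamp_total <- 0L
  meetings_hosted <- 0L
  episodes <- c(play = 0, shop = 0); attempts <- c(play = 0, shop = 0)
  events <- if (keep_events) vector("list", reps) else NULL
  outdoor_types <- ACT_TYPES[OUTDOOR_PLAY_TYPES]

  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, 1000 + r))
    rep_events <- if (keep_events) vector("list", days) else NULL
    for (d in seq_len(days)) {
      ev <- run_day_ctx(ctx, weekday = (d - 1L) %% 5L + 1L)
      clamp_total <- clamp_total + attr(ev, "clamp_count")
      meetings_hosted <- meetings_hosted + attr(ev, "meetings_hosted")
      episodes <- episodes + attr(ev, "episodes")
      attempts <- attempts + attr(ev, "attempts")
      sm <- rowsum(ev$mvpa, ev$agent)
      daily[as.integer(rownames(sm)), d, r] <- sm[, 1]
      ti <- match(ev$type, ACT_TYPES)
      tm <- rowsum(ev$mvpa, ti)
      type_mvpa[as.integer(rownames(tm)), r] <-
        type_mvpa[as.integer(rownames(tm)), r] + tm[, 1]
      wk <- ev$type == "walk"
      if (any(wk)) {
        ws <- rowsum(ev$duration[wk], ev$agent[wk])
        walk_min[as.integer(rownames(ws)), r] <-
          walk_min[as.integer(rownames(ws)), r] + ws[, 1]
      }
      od <- ev$type %in% outdoor_types
      if (any(od)) {
        os <- rowsum(ev$duration[od], ev$agent[od])
        outdoor_min[as.integer(rownames(os)), r] <-
          outdoor_min[as.integer(rownames(os)), r] + os[, 1]
      }
      fs <- ev$type == "fsa"
      if (any(fs)) {
        fsum <- rowsum(ev$duration[fs], ev$agent[fs])
        fsa_min[as.integer(rownames(fsum)), r] <-
          fsa_min[as.integer(rownames(fsum)), r] + fsum[, 1]
      }
      acc_min <- function(mat, sel) {
        if (any(sel)) {
          sm2 <- rowsum(ev$duration[sel], ev$agent[sel])
          idx2 <- as.integer(rownames(sm2))
          mat[idx2, r] <- mat[idx2, r] + sm2[, 1]
        }
        mat
      }
      as_min <- acc_min(as_min, ev$type == "play_after_school")
      meet_min <- acc_min(meet_min, ev$type %in%
                            c("friend_meeting_indoor",
                              "friend_meeting_outdoor"))
      neigh_min <- acc_min(neigh_min, ev$type == "play_neighbourhood")
      if (keep_events) { ev$day <- d; rep_events[[d]] <- ev }
    }
    if (keep_events) events[[r]] <- do.call(rbind, rep_events)
  }

  ag <- pop$agents
  res <- list(
    scenario = sc_id, params = params, seed = seed, days = days, reps = reps,
    agents = ag[, c("id", "zone", "simd_quintile", "sep", "gender",
                    "n_cars", "A", "O", "fsa_count")],
    daily = daily,
    rep_mean_daily = apply(daily, c(1, 3), mean),
    type_mvpa = type_mvpa,
    walk_min = walk_min / days, outdoor_min = outdoor_min / days,
    fsa_min = fsa_min / days, as_min = as_min / days,
    meet_min = meet_min / days, neigh_min = neigh_min / days,
    attempt_rates = attempt_rates, clamp_count = clamp_total,
    counters = list(meetings_hosted = meetings_hosted, episodes = episodes,
                    attempts = attempts),
    events = events)
  class(res) <- "pa_run"
  res
}

#' Calibrate weekly activity frequencies against a time-use target
#'
#' Simulates every combination in the grid and selects the one whose mean
#' daily minutes spent in outdoor play plus organised sport comes closest to
#' the target (UK time-use surveys put this around 50 min/day for 9-11 year
#' olds). Ties are broken towards lower frequencies.
#'
#' A scalar target reproduces the headline total; because quite different
#' frequency combinations can produce the same total, the target may instead
#' be a named vector with entries `after_school`, `meetings` and
#' `neighbourhood` (mean daily minutes per activity, as time-use surveys
#' report them), which identifies each frequency separately. The fit is then
#' the summed absolute deviation over the profile.
#'
#' @param env,pop environment and population.
#' @param grid data.frame with columns `F_as`, `F_friend`, `F_neigh`, or a
#'   list of candidate values expanded to a full grid.
#' @param target_minutes target mean daily outdoor-play + sport minutes, or
#'   a named per-activity profile (see Details).
#' @param days,reps protocol per combination (defaults 10 and 2).
#' @param seed integer seed (shared across combinations: paired comparison).
#' @param base_params baseline `pa_params`.
#' @return list with `best` (the selected row), `target_minutes` and `table`
#'   (the full fit table, one row per combination).
#' @export
calibrate_frequencies <- function(env, pop,
                                  grid = list(F_as = c(1, 2, 3) / 5,
                                              F_friend = c(1, 2, 3) / 5,
                                              F_neigh = c(1, 2, 3) / 5),
                                  target_minutes = 50, days = 10, reps = 2,
                                  seed = 1, base_params = sim_params()) {
  if (!is.data.frame(grid)) grid <- expand.grid(grid)
  stopifnot(all(c("F_as", "F_friend", "F_neigh") %in% names(grid)))
  profile <- !is.null(names(target_minutes)) && length(target_minutes) > 1
  if (profile) {
    need <- c("after_school", "meetings", "neighbourhood")
    stopifnot(all(need %in% names(target_minutes)))
  }
  sim_min <- numeric(nrow(grid))
  fit <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- unclass(base_params)
    p$F_as <- grid$F_as[g]; p$F_friend <- grid$F_friend[g]
    p$F_neigh <- grid$F_neigh[g]
    class(p) <- "pa_params"
    run <- run_experiment(env, pop, sc = NULL, days = days, reps = reps,
                          seed = seed, base_params = p)
    sim_min[g] <- mean(run$outdoor_min + run$fsa_min)
    fit[g] <- if (profile) {
      abs(mean(run$as_min) - target_minutes[["after_school"]]) +
        abs(mean(run$meet_min) - target_minutes[["meetings"]]) +
        abs(mean(run$neigh_min) - target_minutes[["neighbourhood"]])
    } else {
      abs(sim_min[g] - target_minutes)
    }
  }
  tab <- cbind(grid, sim_minutes = sim_min, fit = fit)
  ord <- order(tab$fit, tab$F_as + tab$F_friend + tab$F_neigh,
               tab$F_as, tab$F_friend, tab$F_neigh)
  list(best = tab[ord[1], , drop = FALSE], target_minutes = target_minutes,
       table = tab)
}
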