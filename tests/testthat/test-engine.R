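test_that("a day with no optional activities is commute, school and home", {
  env <- small_env()
  cfg0 <- population_config(fsa_mean_per_sep = c(AB = 0, C1 = 0, C2 = 0,
                                                 DE = 0),
                            cars_by_quintile = matrix(rep(c(1, 0, 0),
                                                          each = 5), 5, 3))
  pop <- synthesize_agents(env, cfg0, seed = 4)
  p <- sim_params(F_as = 0, F_friend = 0, F_neigh = 0, F_shop = 0)
  ev <- run_day(env, pop, p, weekday = 1, seed = 3)
  expect_true(all(ev$type %in% c("walk", "lesson", "recess", "pe", "home")))
  # everyone walks (no cars); per-agent structure: morning walk (if any
  # distance), lessons, recess, maybe PE, walk home, idle at home
  for (i in c(1, 10, 20)) {
    evi <- ev[ev$agent == i, ]
    expect_true(sum(evi$type == "home") == 1)
    expect_lte(sum(evi$type == "pe"), 1)
  }
})

test_that("events tile the 09:00-20:00 day with no gaps or overlaps", {
  env <- small_env()
  pop <- small_pop()
  p <- sim_params()
  for (wd in c(1, 4)) {
    ev <- run_day(env, pop, p, weekday = wd, seed = 100 + wd)
    daywin <- ev[ev$start >= p$day_start, ]
    for (i in seq_len(nrow(pop$agents))) {
      evi <- daywin[daywin$agent == i, ]
      evi <- evi[order(evi$start), ]
      expect_equal(sum(evi$duration), 660)
      expect_equal(evi$start[1], p$day_start)
      if (nrow(evi) > 1) {
        expect_equal(evi$start[-1], (evi$start + evi$duration)[-nrow(evi)])
      }
    }
  }
})

test_that("PE happens exactly once per week per agent plus scenario extras", {
  env <- small_env()
  pop <- small_pop()
  ctxless_week <- function(params, seed) {
    set.seed(seed)
    ctx <- precompute_context(env, pop, params)
    ctx$q_neigh <- 0.03; ctx$q_shop <- 0.03; ctx$q_friend <- params$F_friend
    do.call(rbind, lapply(1:5, function(wd) {
      ev <- mvpasim:::run_day_ctx(ctx, wd)
      ev$day <- wd
      ev
    }))
  }
  week <- ctxless_week(sim_params(), seed = 21)
  pe <- week[week$type == "pe", ]
  cnt <- table(factor(pe$agent, levels = seq_len(nrow(pop$agents))))
  expect_true(all(cnt == 1))
  expect_true(all(pe$duration == 60))
  # +30 min daily PE converts lesson minutes inside the fixed school day
  week4 <- ctxless_week(apply_scenario(sim_params(), "S4"), seed = 21)
  pe4 <- week4[week4$type == "pe", ]
  cnt4 <- tapply(pe4$duration, factor(pe4$agent,
                                      levels = seq_len(nrow(pop$agents))), sum)
  expect_true(all(cnt4 == 5 * 30 + 60))
  lessons <- tapply(week4$duration[week4$type == "lesson"],
                    week4$agent[week4$type == "lesson"], sum)
  expect_true(all(lessons == 5 * 320 - cnt4))
})

test_that("the daily procedure is deterministic for a fixed seed", {
  env <- small_env()
  pop <- small_pop()
  ev1 <- run_day(env, pop, sim_params(), weekday = 3, seed = 77)
  ev2 <- run_day(env, pop, sim_params(), weekday = 3, seed = 77)
  expect_identical(ev1, ev2)
  ev3 <- run_day(env, pop, sim_params(), weekday = 3, seed = 78)
  expect_false(identical(ev1, ev3))
})

test_that("car journeys accumulate zero MVPA and walks accumulate some", {
  env <- small_env()
  pop <- small_pop()
  ev <- run_day(env, pop, sim_params(), weekday = 1, seed = 55)
  cars <- ev[ev$type == "car", ]
  if (nrow(cars) > 0) expect_true(all(cars$mvpa == 0))
  walks <- ev[ev$type == "walk", ]
  expect_gt(sum(walks$mvpa), 0)
})

test_that("deprivation suppresses outdoor play (paired populations)", {
  env <- small_env()
  pop <- small_pop()
  pop_s1 <- pop; pop_s1$agents$s <- 1
  pop_s06 <- pop; pop_s06$agents$s <- 0.6
  count_play <- function(pp, seed) {
    ev <- run_day(env, pp, sim_params(lambda = 0), weekday = 1, seed = seed)
    sum(ev$type %in% c("play_after_school", "play_neighbourhood"))
  }
  tot1 <- sum(vapply(1:12, function(s) count_play(pop_s1, s), 0))
  tot06 <- sum(vapply(1:12, function(s) count_play(pop_s06, s), 0))
  expect_gt(tot1, tot06)
})
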