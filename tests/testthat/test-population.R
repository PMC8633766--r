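test_that("agent attributes follow the configured distributions", {
  env <- cached("pop_env", function() {
    synthetic_city(city_spec(nx = 4, ny = 4, homes_per_zone = 40,
                             schools = 2), seed = 11)
  })
  pop <- cached("pop_big", function() {
    synthesize_agents(env, population_config(), seed = 5)
  })
  ag <- pop$agents
  n <- nrow(ag)
  expect_equal(n, 4 * 4 * 40)
  # gender within 3 SD of 50%
  pg <- mean(ag$gender == "girl")
  expect_lt(abs(pg - 0.5), 3 * sqrt(0.25 / n))
  # A and O: mean within 3 SE of 1 (truncation at 0 is negligible at sd 0.3),
  # sd within 5% of 0.3
  for (v in list(ag$A, ag$O)) {
    expect_lt(abs(mean(v) - 1), 3 * 0.3 / sqrt(n))
    expect_lt(abs(sd(v) - 0.3) / 0.3, 0.05)
  }
  expect_true(all(ag$A > 0) && all(ag$O > 0))
  # deterministic
  pop2 <- synthesize_agents(env, population_config(), seed = 5)
  expect_identical(pop2$agents, ag)
  expect_identical(pop2$friends, pop$friends)
})

test_that("degenerate configurations are honoured", {
  env <- small_env()
  pop <- synthesize_agents(env, population_config(A_sd = 0), seed = 1)
  expect_true(all(pop$agents$A == 1))
  cfg <- population_config(
    sep_by_quintile = matrix(rep(c(0, 0, 0, 1), each = 5), 5, 4))
  popDE <- synthesize_agents(env, cfg, seed = 1)
  expect_true(all(popDE$agents$sep == "DE"))
  expect_error(population_config(
    sep_by_quintile = matrix(rep(c(0.5, 0.1, 0.1, 0.1), each = 5), 5, 4)),
    "sum to 1")
})

test_that("sport-session counts reproduce the SEP gradient", {
  env <- cached("pop_env", function() {
    synthetic_city(city_spec(nx = 4, ny = 4, homes_per_zone = 40,
                             schools = 2), seed = 11)
  })
  pop <- cached("pop_big", function() {
    synthesize_agents(env, population_config(), seed = 5)
  })
  ag <- pop$agents
  m <- tapply(ag$fsa_count, factor(ag$sep, c("AB", "C1", "C2", "DE")), mean)
  expect_true(all(diff(m) <= 0))                 # monotone AB >= ... >= DE
  # about 2:1 under defaults; the ratio of two sample means over ~170
  # agents per band carries a few tenths of Monte-Carlo spread
  expect_gt(m[["AB"]] / m[["DE"]], 1.5)
  expect_lt(m[["AB"]] / m[["DE"]], 2.7)
  expect_true(all(ag$fsa_count <= 5))
  # sessions on distinct weekdays, venue assigned wherever a day is set
  expect_equal(rowSums(pop$fsa$days), ag$fsa_count)
  expect_true(all(is.na(pop$fsa$venue) | pop$fsa$days))
  # zero means give a sport-free population
  cfg0 <- population_config(fsa_mean_per_sep = c(AB = 0, C1 = 0, C2 = 0,
                                                 DE = 0))
  pop0 <- synthesize_agents(small_env(), cfg0, seed = 2)
  expect_true(all(pop0$agents$fsa_count == 0))
})

test_that("sport venues are of eligible kinds", {
  pop <- small_pop()
  env <- small_env()
  venues <- unique(as.integer(pop$fsa$venue[!is.na(pop$fsa$venue)]))
  expect_true(all(env$sites$kind[venues] %in%
                  c("leisure_centre", "sports_field", "school")))
})

test_that("friendship networks are symmetric, within school, degree 3-8", {
  pop <- cached("pop_big", function() {
    env <- cached("pop_env", function() {
      synthetic_city(city_spec(nx = 4, ny = 4, homes_per_zone = 40,
                               schools = 2), seed = 11)
    })
    synthesize_agents(env, population_config(), seed = 5)
  })
  deg <- lengths(pop$friends)
  expect_true(all(deg >= 3 & deg <= 8))
  for (i in sample(length(pop$friends), 50)) {
    for (j in pop$friends[[i]]) {
      expect_true(i %in% pop$friends[[j]])
      expect_identical(pop$agents$school[i], pop$agents$school[j])
    }
  }
})

test_that("tiny schools cap the degree at school size minus one", {
  env <- synthetic_city(city_spec(nx = 2, ny = 1, homes_per_zone = 2,
                                  schools = 1, parks = 1, gardens = 1,
                                  sports_fields = 1, amenities = 1,
                                  leisure_centres = 1, shops = 1), seed = 2)
  pop <- synthesize_agents(env, population_config(), seed = 2)   # 4 pupils
  expect_true(all(lengths(pop$friends) <= 3))
})

test_that("population CSV export round-trips the agent table", {
  pop <- small_pop()
  dir <- withr::local_tempdir()
  write_population_csv(pop, file.path(dir, "agents.csv"),
                       file.path(dir, "edges.csv"))
  back <- read.csv(file.path(dir, "agents.csv"))
  expect_equal(nrow(back), nrow(pop$agents))
  edges <- read.csv(file.path(dir, "edges.csv"))
  expect_equal(nrow(edges), sum(lengths(pop$friends)) / 2)
})
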