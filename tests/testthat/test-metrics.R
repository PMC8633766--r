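# builds a miniature pa_run by hand so summaries can be checked on paper
fake_run <- function() {
  daily <- array(0, dim = c(3, 2, 2))
  daily[, , 1] <- rbind(c(70, 70), c(50, 58), c(80, 90))
  daily[, , 2] <- rbind(c(70, 70), c(54, 50), c(70, 100))
  type_mvpa <- matrix(0, 12, 2,
                      dimnames = list(mvpasim:::ACT_TYPES, NULL))
  type_mvpa["walk", ] <- c(100, 120)
  type_mvpa["recess", ] <- c(200, 180)
  structure(list(
    scenario = "S1", days = 2, reps = 2,
    agents = data.frame(id = c("a", "b", "c"), zone = 1, simd_quintile = 1,
                        sep = c("AB", "DE", "DE"), gender = "girl",
                        n_cars = c(0, 1, 2), A = c(1, 0.8, 1.2),
                        O = c(1, 1, 1), fsa_count = c(2, 0, 1)),
    daily = daily,
    rep_mean_daily = apply(daily, c(1, 3), mean),
    type_mvpa = type_mvpa,
    walk_min = matrix(c(10, 20, 30, 10, 20, 30), 3, 2),
    outdoor_min = matrix(5, 3, 2),
    fsa_min = matrix(c(12, 0, 6), 3, 2),
    clamp_count = 0L), class = "pa_run")
}

test_that("summary statistics match a pencil-and-paper computation", {
  s <- mvpa_summary(fake_run())
  # agent means per rep: rep1 (70, 54, 85), rep2 (70, 52, 85)
  expect_equal(s$mean_mvpa, mean(c(mean(c(70, 54, 85)),
                                   mean(c(70, 52, 85)))))
  expect_equal(s$pct_below, 100 * mean(c(1 / 3, 1 / 3)))
  # agent b dips below 60 on every day; agents a and c never do
  expect_equal(s$pct_always, 100 * 2 / 3)
  expect_equal(sum(s$share_by_type), 100, tolerance = 1e-8)
  expect_equal(unname(s$share_by_type["walk"]), 100 * 220 / 600)
  expect_equal(unname(s$mean_by_sep[["AB"]]), 70)
  expect_equal(unname(s$mean_by_sep[["DE"]]), mean(c(53, 85)))
  expect_true(is.na(s$mean_by_sep[["C1"]]))
})

test_that("a population at a constant 70 min never falls below guideline", {
  run <- fake_run()
  run$daily[] <- 70
  run$rep_mean_daily <- apply(run$daily, c(1, 3), mean)
  s <- mvpa_summary(run)
  expect_equal(s$pct_below, 0)
  expect_equal(s$pct_always, 100)
  expect_equal(s$mean_mvpa, 70)
})

test_that("correlations behave on perfect, null and degenerate attributes", {
  run <- fake_run()
  # make MVPA identical to walking time -> r = 1
  run$rep_mean_daily <- run$walk_min
  ct <- correlate(run)
  expect_equal(ct$r[ct$attribute == "walking_time"], 1)
  # zero-variance attribute reported as NA, not 0
  expect_true(is.na(ct$r[ct$attribute == "O"]))
  expect_true(is.na(ct$r[ct$attribute == "simd"]))
  # permuted attribute decorrelates on a larger synthetic ledger
  set.seed(8)
  n <- 400
  big <- fake_run()
  y <- rnorm(n, 60, 10)
  big$rep_mean_daily <- cbind(y, y)
  big$daily <- array(rep(y, 4), dim = c(n, 2, 2))
  big$walk_min <- cbind(y / 2 + rnorm(n), y / 2 + rnorm(n))  # correlated
  big$outdoor_min <- matrix(rnorm(2 * n, 20, 5), n, 2)       # independent
  big$agents <- data.frame(id = seq_len(n), zone = 1,
                           simd_quintile = sample(1:5, n, TRUE),
                           sep = "AB", gender = "girl",
                           n_cars = sample(0:2, n, TRUE),
                           A = sample(y) / 60, O = rnorm(n, 1, 0.3),
                           fsa_count = sample(0:5, n, TRUE))
  ct2 <- correlate(big)
  r_perm <- ct2$r[ct2$attribute == "A"]     # permuted copy of y: independent
  expect_lt(abs(r_perm), 3 / sqrt(n))
  expect_gt(ct2$r[ct2$attribute == "walking_time"], 0.9)
})

test_that("the KS statistic equals the brute-force ECDF gap", {
  brute_D <- function(a, b) {
    xs <- sort(unique(c(a, b)))
    max(abs(vapply(xs, function(x) mean(a <= x) - mean(b <= x), 0)))
  }
  set.seed(11)
  a <- c(12, 55, 33, 91, 40); b <- c(18, 52, 60, 77, 39)
  res <- ks_two_sample(a, b)
  expect_equal(res$D, brute_D(a, b))
  for (k in 1:5) {
    x <- rnorm(30, 60, 15); y <- rnorm(40, 65, 12)
    expect_equal(ks_two_sample(x, y)$D, brute_D(x, y), tolerance = 1e-12)
  }
  expect_equal(ks_two_sample(a, a)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
})
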