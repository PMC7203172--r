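all_on_series <- function(horizon) {
  structure(list(t_end = horizon, switch_times = numeric(0), state_0 = 1L),
            class = "switch_series")
}

test_that("uninterrupted growth follows the closed form exactly", {
  tp <- tech_params(alpha = 0.345, T_init = 1e13, T_target = 4e26)
  s <- all_on_series(100)
  path <- integrate_technology(s, tp)
  t_double <- log(2) / tp$alpha
  expect_equal(tech_level(path, t_double), 2e13, tolerance = 1e-12)
  # time from 1e13 to 4e26 W at alpha = 0.345 is (1/alpha) ln(4e13) ~ 90.8 yr
  fpt <- first_passage_time(s, tp)
  expect_false(fpt$censored)
  expect_equal(fpt$time, log(4e13) / 0.345, tolerance = 1e-12)
  expect_equal(fpt$time, 90.78, tolerance = 1e-3)
})

test_that("the level freezes in the off state", {
  s <- structure(list(t_end = 50, switch_times = numeric(0), state_0 = 0L),
                 class = "switch_series")
  tp <- tech_params()
  path <- integrate_technology(s, tp)
  expect_equal(tech_level(path, c(0, 25, 50)), rep(1e13, 3))
  expect_true(first_passage_time(s, tp)$censored)
})

test_that("exact piecewise integration agrees with a fine Euler oracle", {
  tp <- tech_params(alpha = 0.5, T_init = 1, T_target = 1e30)
  s <- sample_switch_series(cycle_spec(), horizon = 40, seed = 3)
  path <- integrate_technology(s, tp)
  # independent brute-force oracle: Euler steps through the same noise
  h <- 1e-4
  tgrid <- seq(0, 40, by = h)
  xi <- eval_switch_series(s, tgrid)
  logT <- cumsum(c(0, tp$alpha * h * xi[-length(xi)]))
  for (tt in c(7.3, 19.9, 40)) {
    i <- round(tt / h) + 1
    expect_equal(tech_level(path, tt), exp(logT[i]), tolerance = 1e-3)
  }
})

test_that("first passage is solved exactly on the crossing on-interval", {
  # on over [1,3) and [4,...): crossing after 2.5 yr of on-time is at t=4.5
  s <- structure(list(t_end = 20, switch_times = c(1, 3, 4), state_0 = 0L),
                 class = "switch_series")
  tp <- tech_params(alpha = 1, T_init = 1, T_target = exp(2.5))
  expect_equal(first_passage_time(s, tp)$time, 4.5, tolerance = 1e-12)
  # target exactly at the end of an on-interval
  tp2 <- tech_params(alpha = 1, T_init = 1, T_target = exp(2))
  expect_equal(first_passage_time(s, tp2)$time, 3, tolerance = 1e-12)
})

test_that("sampled passage times respect the hard lower bound", {
  tp <- moore_tech()
  lower <- min_passage_time(tp)
  for (spec in list(cycle_spec(),
                    dichotomous_spec(mode = "symmetric-rate", gamma = 4))) {
    x <- sample_fpt_batch(spec, tp, n = 2000, seed = 13)
    expect_true(all(x >= lower - 1e-9))
  }
})

test_that("renewal mean of the passage time matches theory", {
  # with off/on means (m0, m1), E[FPT] = S (1 + m0/m1) + initial-state term;
  # for (1, 4) and S = 90.78 the renewal value is ~113.5 yr
  tp <- moore_tech()
  x <- sample_fpt_batch(dichotomous_spec(mean_off = 1, mean_on = 4), tp,
                        n = 6000, seed = 29)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - min_passage_time(tp) / 0.8), 3 * se + 0.25)
})

test_that("mean passage time decreases with the growth rate", {
  spec <- cycle_spec()
  means <- vapply(c(0.5, 1, 2), function(a) {
    mean(sample_fpt_batch(spec, tech_params(alpha = a), n = 1500, seed = 31))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("batch sampler and series-based passage agree in distribution", {
  # dual route: the vectorised sampler versus explicit switch-series
  # realisations fed through the exact integrator
  spec <- dichotomous_spec(mean_off = 2, mean_on = 2)
  tp <- tech_params(alpha = 1, T_init = 1, T_target = exp(10))
  batch <- sample_fpt_batch(spec, tp, n = 1500, seed = 17)
  via_series <- vapply(seq_len(1500), function(i) {
    s <- sample_switch_series(spec, horizon = 200, seed = 100000 + i)
    first_passage_time(s, tp)$time
  }, numeric(1))
  expect_lt(suppressWarnings(stats::ks.test(batch, via_series)$statistic), 0.05)
})

test_that("passage sampling is seed-deterministic and censors correctly", {
  spec <- cycle_spec()
  tp <- moore_tech()
  expect_identical(sample_fpt_batch(spec, tp, 100, seed = 8),
                   sample_fpt_batch(spec, tp, 100, seed = 8))
  hard_min <- min_passage_time(tp)
  expect_true(all(is.na(sample_fpt_batch(spec, tp, 100,
                                         deadline = hard_min * 0.9,
                                         seed = 8))))
  # degenerate target: crossing at t = 0
  tp0 <- tech_params(alpha = 1, T_init = 1e13, T_target = 1e13)
  expect_equal(sample_fpt_batch(spec, tp0, 5, seed = 1), rep(0, 5))
})

test_that("empirical distribution object reports censoring and histogram", {
  spec <- dichotomous_spec(mode = "symmetric-rate", gamma = 1)
  fpt <- empirical_fpt_distribution(spec, moore_tech(), n = 400, seed = 21)
  expect_length(fpt$times, 400)
  expect_false(any(fpt$censored))
  expect_s3_class(fpt, "fpt_samples")
  expect_true(all(c("mid", "density") %in% names(fpt$histogram)))
  # symmetric mode defaults to a growth-state start for the validation
  expect_equal(fpt$spec$initial_state_rule, "fixed-on")
  path <- tempfile(fileext = ".csv")
  write_fpt_csv(fpt, path, seed = 21)
  got <- utils::read.csv(path)
  expect_identical(names(got),
                   c("trial", "seed", "first_passage_years", "censored"))
  unlink(path)
})
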