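test_that("decoupled limit reproduces the closed-form logistic", {
  # with a0 = 0 and R0 = R_c the forest stays at R_c and N is a pure
  # logistic with carrying capacity beta * R_c
  p <- forest_params(beta = 170, a0 = 0, R0 = 6e7)
  traj <- integrate_humans_forest(p, horizon = 50, step = 0.001)
  K <- p$beta * p$R_c
  closed <- K * p$N0 * exp(p$r * traj$t) /
    (K + p$N0 * (exp(p$r * traj$t) - 1))
  expect_equal(traj$R, rep(p$R_c, nrow(traj)), tolerance = 1e-12)
  expect_lt(max(abs(traj$N - closed) / closed), 1e-3)
  expect_false(find_no_return(traj)$found)
})

test_that("baseline runs peak and collapse at the expected times", {
  nr170 <- find_no_return(integrate_humans_forest(baseline_forest(170)))
  nr700 <- find_no_return(integrate_humans_forest(baseline_forest(700)))
  expect_true(nr170$found)
  expect_true(nr700$found)
  # population maximum ~22 yr (beta = 170) and ~130 yr (beta = 700),
  # within 10% to absorb step/detection conventions
  expect_lt(abs(nr170$t_nr - 22) / 22, 0.10)
  expect_lt(abs(nr700$t_nr - 130) / 130, 0.10)
  # peak population for beta = 700 is ~1e10 (the Earth carrying capacity)
  expect_lt(abs(log(nr700$N_max / 1e10)), log(1.5))
})

test_that("Euler state stays positive and the peak time is step-converged", {
  for (beta in c(170, 700)) {
    tr <- integrate_humans_forest(baseline_forest(beta), horizon = 500,
                                  step = 0.01)
    expect_gt(min(tr$N), 0)
    expect_gt(min(tr$R), 0)
    t1 <- find_no_return(tr)$t_nr
    t2 <- find_no_return(integrate_humans_forest(baseline_forest(beta),
                                                 horizon = 500,
                                                 step = 0.005))$t_nr
    expect_lt(abs(t1 - t2) / t1, 0.01)
  }
})

test_that("collapse time responds monotonically to extraction and capacity", {
  t_nr_a <- vapply(c(5e-13, 1e-12, 2e-12), function(a0) {
    find_no_return(integrate_humans_forest(baseline_forest(170, a0 = a0)))$t_nr
  }, numeric(1))
  expect_true(all(diff(t_nr_a) <= 0)) # more extraction, earlier collapse
  t_nr_b <- vapply(c(170, 300, 700), function(beta) {
    find_no_return(integrate_humans_forest(baseline_forest(beta)))$t_nr
  }, numeric(1))
  expect_true(all(diff(t_nr_b) >= 0)) # more capacity, later collapse
})

test_that("continental rescaling is an exact change of units", {
  p <- baseline_forest(170)
  ps <- rescale_to_continental(p)
  expect_equal(ps$a0, 1.5e-4) # a = a0 * R_W
  expect_true(ps$rescaled)
  tr <- integrate_humans_forest(p, horizon = 100)
  trs <- integrate_humans_forest(ps, horizon = 100)
  expect_lt(max(abs(trs$N * p$R_W - tr$N) / tr$N), 1e-9)
  expect_lt(max(abs(trs$R * p$R_W - tr$R) / tr$R), 1e-9)
  # round trip restores the original parameters
  back <- unrescale_from_continental(ps)
  expect_equal(back[names(back) != "rescaled"], p[names(p) != "rescaled"])
  # R_W = 1 makes the transform the identity
  p1 <- forest_params(beta = 170, R_W = 1)
  expect_equal(rescale_to_continental(p1)$a0, p1$a0)
})

test_that("no-return detection requires an interior maximum plus decline", {
  fake <- function(N) {
    structure(data.frame(t = seq_along(N) - 1, N = N, R = rep(1, length(N))),
              class = c("population_trajectory", "data.frame"))
  }
  expect_false(find_no_return(fake(1:50))$found)           # monotone rise
  expect_false(find_no_return(fake(50:1))$found)           # falls from t = 0
  # numerical plateau: a dip far below the 1% decline threshold is ignored
  expect_false(find_no_return(fake(c(1:10, rep(10 * 0.9999999, 10))))$found)
  peaked <- fake(c(seq(1, 2, length.out = 20), seq(2, 0.5, length.out = 20)[-1]))
  nr <- find_no_return(peaked)
  expect_true(nr$found)
  expect_equal(nr$N_max, 2)
})

test_that("parameter estimators reproduce the planetary values", {
  expect_equal(estimate_beta(1e10, 6e7), 166.6667, tolerance = 1e-4)
  expect_equal(estimate_beta(42, 42), 1)
  expect_equal(estimate_beta(2e10, 6e7), 2 * estimate_beta(1e10, 6e7))
  expect_error(estimate_beta(1e10, 0), "positive")

  a0 <- estimate_a0(3e7, 2.3e6, 12, 7.5e9)
  expect_equal(a0, 8.5185e-13, tolerance = 1e-4)
  expect_equal(round(log10(a0)), -12) # order of magnitude 1e-12
  expect_equal(estimate_a0(3e7, 0, 12, 7.5e9), 0)
  expect_equal(estimate_a0(3e7, 2.3e6, 12, 1.5e10), a0 / 2)
  expect_error(estimate_a0(0, 2.3e6, 12, 7.5e9), "positive")
})

test_that("invalid parameters and steps are rejected with clear errors", {
  expect_error(forest_params(beta = -1), "beta")
  expect_error(forest_params(R0 = 7e7), "R_c")
  expect_error(forest_params(a0 = -1e-12), "a0")
  # a grossly overlarge step must fail loudly and name the step
  expect_error(integrate_humans_forest(baseline_forest(170), horizon = 500,
                                       step = 150), "step 150")
})

test_that("trajectory CSV export has the documented schema", {
  tr <- integrate_humans_forest(baseline_forest(170), horizon = 5, step = 0.1)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path, every = 10)
  got <- utils::read.csv(path)
  expect_identical(names(got), c("t", "calendar_year", "N", "R"))
  expect_equal(got$calendar_year[1], 2000)
  expect_equal(got$N[1], 6e9)
  unlink(path)
})
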