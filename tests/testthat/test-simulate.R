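# Simulation, dose mapping, percent-CAR observables, response times and
# global-maximum normalization.

test_that("dose mapping is linear in dose through both channels", {
  dc <- dose_condition(2, alpha_d_at_1uM = 0.5, oht0_at_1uM = 0.25)
  expect_equal(dc$alpha_d, 1)
  expect_equal(dc$oht0, 0.5)
  expect_equal(dose_condition(0)$alpha_d, 0)
  expect_error(dose_condition(-1), ">= 0")
})

test_that("genomic total is conserved to 1e-6 over ten days", {
  traj <- simulate_switch(default_truth(), dose = dose_condition(1),
                          t_grid = seq(0, 10, by = 0.25))
  dna <- traj$D_S1 + traj$D_tS1 + traj$D_tS2 + traj$D_S2
  expect_lt(max(abs(dna / dna[1] - 1)), 1e-6)
})

test_that("halving solver tolerances moves percent CAR by < 0.1 points", {
  p <- default_truth()
  s1 <- solver_config(rtol = 1e-6, atol = 1e-8)
  s2 <- solver_config(rtol = 5e-7, atol = 5e-9)
  g <- seq(0, 10, by = 0.5)
  a <- percent_car(simulate_switch(p, dose_condition(1), g, s1), "ON")
  b <- percent_car(simulate_switch(p, dose_condition(1), g, s2), "ON")
  expect_lt(max(abs(a$percent - b$percent)), 0.1)
})

test_that("percent CAR follows its defining arithmetic", {
  mk <- function(S1, tS1, tS2, SX, S2) {
    traj <- tibble::tibble(time = 0, F = 0, OHT = 0, Fa = 0, Fb = 0,
                           D_S1 = S1, D_tS1 = tS1, D_tS2 = tS2,
                           D_SX = SX, D_S2 = S2)
    attr(traj, "model") <- "reduced"
    class(traj) <- c("switch_trajectory", class(traj))
    traj
  }
  expect_equal(percent_car(mk(1, 0, 0, 0, 0), "ON")$percent, 0)
  expect_equal(percent_car(mk(1, 0, 0, 0, 0), "OFF")$percent, 100)
  expect_equal(percent_car(mk(0.25, 0.25, 0.25, 0, 0.25), "ON")$percent, 75)
  # ON and OFF observables are exact complements of the same state
  set.seed(8)
  for (i in 1:10) {
    tr <- mk(runif(1), runif(1), runif(1), runif(1), runif(1))
    expect_equal(percent_car(tr, "ON")$percent +
                   percent_car(tr, "OFF")$percent, 100)
  }
  expect_error(percent_car(mk(0, 0, 0, 1, 0), "ON"), "zero genomic")
})

test_that("response time interpolates the 90% crossing", {
  lin <- tibble::tibble(time = seq(0, 10, by = 0.5),
                        value = 10 * seq(0, 10, by = 0.5))
  rt <- response_time(lin, "ON")
  expect_equal(rt$value, 9, tolerance = 1e-12)
  expect_false(rt$censored)

  const <- tibble::tibble(time = 0:10, value = rep(50, 11))
  expect_equal(response_time(const, "ON")$value, 0)

  fall <- tibble::tibble(time = seq(0, 10, by = 0.1),
                         value = 100 * exp(-0.5 * seq(0, 10, by = 0.1)))
  rt_off <- response_time(fall, "OFF")
  drop90 <- fall$value[1] - 0.9 * (fall$value[1] - min(fall$value))
  expect_equal(100 * exp(-0.5 * rt_off$value), drop90, tolerance = 1e-3)

  flat <- tibble::tibble(time = 0:10, value = c(0:9, 9.05))
  expect_false(response_time(flat, "ON")$censored)
  expect_error(response_time(tibble::tibble(time = numeric(),
                                            value = numeric()), "ON"),
               "empty")
})

test_that("interpolated response time matches the dense-scan oracle", {
  traj <- simulate_switch(default_truth(), dose = dose_condition(1),
                          t_grid = seq(0, 10, by = 0.05))
  on <- percent_car(traj, "ON")
  rt <- response_time(on, "ON")
  scan <- oracle_response_time(on$time, on$percent, "ON")
  expect_lt(abs(rt$value - scan), 1e-4 + 0.05)
  # refinement converges toward the oracle
  traj2 <- simulate_switch(default_truth(), dose = dose_condition(1),
                           t_grid = seq(0, 10, by = 0.005))
  on2 <- percent_car(traj2, "ON")
  expect_lt(abs(response_time(on2, "ON")$value - scan), 0.01)
})

test_that("global-max normalization rescales to 100 and is homogeneous", {
  set.seed(21)
  d <- tibble::tibble(switch = "ON", dose_uM = 1, day = 1:10,
                      percent_car = runif(10, 5, 80))
  n1 <- normalize_to_global_max(d)
  expect_equal(max(n1$percent_car), 100)
  expect_equal(order(n1$percent_car), order(d$percent_car))

  d2 <- d; d2$percent_car <- d2$percent_car / 2
  expect_equal(normalize_to_global_max(d2)$percent_car, n1$percent_car)

  d3 <- d; d3$percent_car[1] <- 100
  d3$percent_car <- d3$percent_car * (100 / max(d3$percent_car))
  expect_equal(normalize_to_global_max(d3)$percent_car, d3$percent_car)

  expect_error(normalize_to_global_max(
    tibble::tibble(percent_car = c(0, 0))), "all-zero")
})
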