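# Sensitivity, dose-response, fold-change and trade-off analyses at the
# shipped synthetic truth.

truth <- default_truth()

test_that("identity perturbation reproduces the baseline exactly", {
  tab <- sensitivity_scan(truth, factor_grid = c(0.5, 1, 2))
  base <- attr(tab, "baseline")
  at1 <- tab[tab$factor == 1, ]
  expect_equal(at1$response_time[at1$switch == "ON"],
               rep(unname(base["ON"]), 12))
  expect_equal(at1$response_time[at1$switch == "OFF"],
               rep(unname(base["OFF"]), 12))
  expect_false(any(at1$censored))
})

test_that("FlpO expression/activation/degradation outrank the
           recombination-step parameters", {
  # directional check at the synthetic truth: the protein/drug-side rates
  # the circuit can be tuned through are more influential on response time
  # than the per-event recombination rates and the loop dilution
  tab <- sensitivity_scan(truth, factor_grid = 10^seq(-2, 2, length.out = 9))
  rk <- sensitivity_ranking(tab)
  s <- stats::setNames(rk$sensitivity, rk$parameter)
  for (nm in c("alpha_a", "beta_p", "beta_d", "K_a")) {
    expect_gt(s[[nm]], max(s[c("k3", "k4", "delta")]))
  }
  expect_true(any(c("alpha_a", "beta_p", "K_a") %in%
                    rk$parameter[rk$rank <= 6]))
})

test_that("doubling the factor-grid density preserves the ranking", {
  r1 <- sensitivity_ranking(
    sensitivity_scan(truth, factor_grid = 10^seq(-2, 2, length.out = 9)))
  r2 <- sensitivity_ranking(
    sensitivity_scan(truth, factor_grid = 10^seq(-2, 2, length.out = 17)))
  expect_equal(r1$parameter, r2$parameter)
})

test_that("ON response time falls monotonically with dose over 0.1-10 uM", {
  curve <- dose_response(truth, dose_grid = 10^seq(-1, 1, length.out = 9))
  on <- curve[curve$switch == "ON", ]
  expect_true(all(diff(on$response_time) <= 1e-6))
})

test_that("zero dose with no leak pathway never switches", {
  p <- truth
  p$alpha_b <- 0; p$K_b <- 0
  curve <- dose_response(p, dose_grid = 0)
  expect_true(all(curve$censored))
  expect_equal(curve$response_time, c(10, 10))
})

test_that("dose-response values equal independent single simulations", {
  curve <- dose_response(truth, dose_grid = c(0.5, 2))
  for (d in c(0.5, 2)) {
    rt <- flpswitch:::response_times_at(truth, d)
    expect_equal(
      curve$response_time[curve$dose_uM == d & curve$switch == "ON"],
      rt$ON$value)
    expect_equal(
      curve$response_time[curve$dose_uM == d & curve$switch == "OFF"],
      rt$OFF$value)
  }
})

test_that("fold scan: identity at fold 1, faster switching and higher basal
           response with increasing FlpO expression", {
  scan <- fold_change_scan(truth, folds = c(1, 2, 5), dt = 0.02)
  base <- simulate_switch(truth, dose = dose_condition(1),
                          t_grid = seq(0, 10, by = 0.02))
  on1 <- scan[scan$fold == 1 & scan$dose_uM == 1 & scan$switch == "ON", ]
  expect_equal(on1$percent, percent_car(base, "ON")$percent,
               tolerance = 1e-9)

  rt <- sapply(c(1, 2, 5), function(f) {
    s <- scan[scan$fold == f & scan$dose_uM == 1 & scan$switch == "ON", ]
    response_time(s[, c("time", "percent")], "ON")$value
  })
  expect_true(all(diff(rt) < 0))

  basal10 <- sapply(c(1, 2, 5), function(f) {
    s <- scan[scan$fold == f & scan$dose_uM == 0 & scan$switch == "ON", ]
    s$percent[which.max(s$time)]
  })
  expect_true(all(diff(basal10) >= 0))
})

test_that("trade-off grid is bounded, spot-checkable, and collapses to the
           dose-response curve at fold 1", {
  fold_grid <- c(0.5, 1, 2)
  dose_grid <- c(0.2, 1, 5)
  grid <- tradeoff_grid(truth, fold_grid = fold_grid, dose_grid = dose_grid)
  expect_true(all(grid$response_time >= 0 & grid$response_time <= 10))

  dr <- dose_response(truth, dose_grid = dose_grid)
  row1 <- grid[grid$fold == 1, c("dose_uM", "switch", "response_time",
                                 "censored")]
  expect_equal(dplyr::arrange(row1, dose_uM, switch),
               dplyr::arrange(dr, dose_uM, switch),
               ignore_attr = TRUE)

  set.seed(6)
  for (i in 1:4) {
    f <- sample(fold_grid, 1); d <- sample(dose_grid, 1)
    pf <- flpswitch:::scale_fitted(
      flpswitch:::scale_fitted(truth, "alpha_a", f), "alpha_b", f)
    rt <- flpswitch:::response_times_at(pf, d)
    expect_equal(
      grid$response_time[grid$fold == f & grid$dose_uM == d &
                           grid$switch == "ON"], rt$ON$value)
  }
})

test_that("scan outputs are pure functions of their inputs", {
  a <- dose_response(truth, dose_grid = c(0.3, 3))
  b <- dose_response(truth, dose_grid = c(0.3, 3))
  expect_identical(a, b)
})
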