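# The distance function and the genetic-algorithm fitter.

test_that("distance follows the sum-over-ten definition", {
  x <- runif(40, 0, 100)
  expect_equal(error_distance(x, x), 0)
  expect_equal(error_distance(rep(1, 40), rep(0, 40)), 4)
  expect_equal(error_distance(rep(0, 40), rep(1, 40)), 4)
  set.seed(13)
  a <- runif(40, 0, 100); b <- runif(40, 0, 100)
  expect_equal(error_distance(a, b), oracle_distance(a, b))
  expect_error(error_distance(1:10, 1:9), "mismatch")
})

test_that("distance joins tidy datasets on their identifying columns", {
  gen <- noiseless_datasets()
  d <- gen$datasets
  expect_equal(error_distance(d, d), 0)
  d2 <- d
  d2$percent_car <- d2$percent_car + 1
  expect_equal(error_distance(d2, d), 4)
  expect_error(error_distance(d[-1, ], d), "one-to-one")
})

test_that("the lean reduced objective agrees with the generic pipeline", {
  gen <- noiseless_datasets()
  obj <- flpswitch:::make_objective(gen$datasets)
  set.seed(4)
  for (i in 1:5) {
    theta <- stats::setNames(runif(12), reduced_fitted_names())
    sim <- flpswitch:::simulate_percent_grid(as_reduced_parameters(theta))
    expect_equal(obj(theta), error_distance(sim, gen$datasets),
                 tolerance = 1e-8)
  }
})

test_that("a perfect candidate seeded into the population survives", {
  gen <- noiseless_datasets()
  truth <- unlist(gen$truth$parameters)[reduced_fitted_names()]
  fit <- fit_ga(gen$datasets,
                config = ga_config(population_size = 20, generations = 5,
                                   seed = 2),
                init_population = matrix(truth, nrow = 1,
                                         dimnames = list(NULL, names(truth))))
  expect_lt(fit$error, 1e-6)
  expect_equal(unname(fit$parameters), unname(truth))
})

test_that("GA runs are reproducible, bounded, and monotone in best error", {
  gen <- noiseless_datasets()
  cfg <- ga_config(population_size = 24, generations = 12, seed = 7)
  f1 <- fit_ga(gen$datasets, config = cfg)
  f2 <- fit_ga(gen$datasets, config = cfg)
  expect_identical(f1$parameters, f2$parameters)
  expect_identical(f1$error, f2$error)
  expect_true(all(f1$parameters >= 0 & f1$parameters <= 1))
  expect_true(all(diff(f1$history) <= 0))
  expect_equal(f1$evaluations, 24 * 13)

  f3 <- fit_ga(gen$datasets, config = ga_config(population_size = 24,
                                                generations = 12, seed = 8))
  expect_false(identical(f1$parameters, f3$parameters))
})

test_that("fit results carry residuals and tidy/glance methods", {
  gen <- noiseless_datasets()
  fit <- fit_ga(gen$datasets, config = ga_config(population_size = 16,
                                                 generations = 4, seed = 1))
  expect_equal(nrow(fit$residuals), 40)
  expect_equal(error_distance(fit$residuals$percent_car_sim,
                              fit$residuals$percent_car_obs),
               fit$error, tolerance = 1e-9)
  td <- generics::tidy(fit)
  expect_equal(td$term, reduced_fitted_names())
  gl <- generics::glance(fit)
  expect_equal(gl$error, fit$error)
  expect_equal(gl$generations, 4L)
})
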