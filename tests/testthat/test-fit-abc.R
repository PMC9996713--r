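# ABC with sequential Monte Carlo: acceptance rule, weights, determinism,
# and posterior summaries.

abc_data <- function() noiseless_datasets()$datasets

test_that("configuration rejects a non-decreasing schedule", {
  expect_error(abc_config(epsilon_schedule = c(10, 10, 5)),
               "strictly decreasing")
  expect_error(abc_config(epsilon_schedule = c(5, 10)),
               "strictly decreasing")
  expect_error(abc_config(n_particles = 0), ">= 1")
})

test_that("a threshold above the maximum distance accepts everything", {
  # d is at most 400 for percentages, so epsilon = 500 accepts all of
  # population 1 drawn from the prior
  res <- abc_smc(abc_data(),
                 config = abc_config(n_particles = 30,
                                     epsilon_schedule = c(500, 60),
                                     seed = 5))
  expect_equal(res$populations[[1]]$acceptance_percent, 100)
  expect_equal(res$populations[[1]]$particles_assessed, 30)
})

test_that("accepted particles satisfy their threshold, stay in the prior box,
           and carry normalized weights", {
  res <- abc_smc(abc_data(),
                 config = abc_config(n_particles = 40,
                                     epsilon_schedule = c(100, 40, 25),
                                     seed = 11))
  expect_equal(length(res$populations), 3)
  for (pop in res$populations) {
    expect_true(all(pop$errors < pop$epsilon))
    expect_true(all(as.matrix(pop$particles) >= 0 &
                      as.matrix(pop$particles) <= 1))
    expect_equal(sum(pop$weights), 1, tolerance = 1e-12)
  }
  expect_equal(res$log$epsilon, c(100, 40, 25))
  expect_false(res$terminated_early)
})

test_that("the particle sequence is seed-deterministic", {
  cfg <- abc_config(n_particles = 20, epsilon_schedule = c(200, 80),
                    seed = 3)
  r1 <- abc_smc(abc_data(), config = cfg)
  r2 <- abc_smc(abc_data(), config = cfg)
  expect_identical(r1$populations[[2]]$particles,
                   r2$populations[[2]]$particles)
  expect_identical(r1$populations[[2]]$weights, r2$populations[[2]]$weights)
})

test_that("an unreachable threshold stops the run after the last filled
           population", {
  res <- abc_smc(abc_data(),
                 config = abc_config(n_particles = 15,
                                     epsilon_schedule = c(200, 1e-8),
                                     max_draws = 300, seed = 9))
  expect_equal(length(res$populations), 1)
  expect_true(res$terminated_early)
  expect_equal(res$reached_epsilon, 200)
})

test_that("posterior concentration: marginal variance shrinks with epsilon", {
  # checked with slack across three seeds
  shrunk <- vapply(c(2, 3, 4), function(s) {
    res <- abc_smc(abc_data(),
                   config = abc_config(n_particles = 40,
                                       epsilon_schedule = c(300, 60, 30),
                                       seed = s))
    v1 <- sapply(res$populations[[1]]$particles, stats::var)
    vL <- sapply(res$populations[[length(res$populations)]]$particles,
                 stats::var)
    mean(vL) < mean(v1)
  }, logical(1))
  expect_gte(sum(shrunk), 2)
})

test_that("weighted posterior summaries behave at the degenerate cases", {
  pop <- structure(list(
    particles = tibble::tibble(a = rep(0.4, 5), b = c(0, 0, 1, 1, 1)),
    weights = rep(0.2, 5), errors = rep(1, 5), epsilon = 10,
    particles_assessed = 5, acceptance_percent = 100),
    class = "abc_population")
  s <- posterior_summary(pop)
  qa <- s$quantiles[s$quantiles$parameter == "a", ]
  expect_true(all(qa[, c("q5", "q25", "q50", "q75", "q95")] == 0.4))

  pop2 <- structure(list(
    particles = tibble::tibble(x = c(0, 1)), weights = c(0.5, 0.5),
    errors = c(1, 1), epsilon = 10, particles_assessed = 2,
    acceptance_percent = 100), class = "abc_population")
  s2 <- posterior_summary(pop2)
  expect_equal(s2$quantiles$q50, 0.5)

  expect_error(posterior_summary(list()), "abc_population")
})
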