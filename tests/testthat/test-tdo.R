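test_that("random-other selection is uniform over the other members", {
  expect_identical(select_random_other(1, 2), 2L)
  expect_error(select_random_other(1, 1), "pop_size")
  expect_error(select_random_other(11, 10), "out of range")
  set.seed(99)
  draws <- replicate(1e4, select_random_other(3, 10))
  expect_false(any(draws == 3))
  freq <- table(factor(draws, levels = setdiff(1:10, 3))) / 1e4
  expect_true(all(abs(freq - 1 / 9) < 0.02))
})

test_that("guided move matches hand arithmetic with stubbed steps", {
  # same point: zero displacement whatever the step multiplier
  expect_equal(tdo_guided_move(c(2, 2), c(2, 2), 1, 0, I = 1, S = 0.7),
               c(2, 2))
  # toward a fitter target, I = 2: 2 + 0.5 * (0 - 2*2) = 0
  expect_equal(tdo_guided_move(2, 0, f_x = 5, f_target = 1, I = 2, S = 0.5),
               0)
  # away from a worse target: 2 + 0.5 * (2 - 0) = 3
  expect_equal(tdo_guided_move(2, 0, f_x = 1, f_target = 5, I = 1, S = 0.5),
               3)
  expect_error(tdo_guided_move(c(1, 2), 1, 0, 0, I = 1), "shape")
  expect_error(tdo_guided_move(1, 1, 0, 0, I = 3), "intensity")
})

test_that("local-search radius shrinks linearly to zero", {
  expect_equal(local_search_radius(0, 100), 0.01)
  expect_equal(local_search_radius(50, 100), 0.005)
  expect_equal(local_search_radius(100, 100), 0)
  expect_error(local_search_radius(101, 100), "out of range")
})

test_that("local-search move is a multiplicative perturbation", {
  expect_equal(local_search_move(c(1, -2), 0), c(1, -2))
  expect_equal(local_search_move(c(0, 0), 0.01), c(0, 0))
  # r = 1: x * (1 + s) = 10 * 1.01
  expect_equal(local_search_move(10, 0.01, r = 1), 10.1)
  set.seed(1)
  x <- rnorm(20)
  moved <- local_search_move(x, 0.01)
  expect_true(all(abs(moved - x) <= 0.01 * abs(x) + 1e-15))
})

test_that("tdo_minimize converges on the 2-D sphere and respects bounds", {
  sphere <- benchmark_function("sphere")
  b <- bounds(-5, 5, dim = 2)
  seen <- new.env(); seen$bad <- 0L
  watched <- objective_function(function(x) {
    if (any(x < -5 - 1e-12) || any(x > 5 + 1e-12)) seen$bad <- seen$bad + 1L
    sum(x^2)
  }, name = "watched-sphere")
  best <- sapply(1:5, function(s) {
    res <- tdo_minimize(watched, b, tdo_config(20, 100, seed = s))
    expect_true(all(diff(res$trace) <= 1e-12))
    expect_equal(res$best_fitness, sphere$fn(res$best_position))
    res$best_fitness
  })
  expect_equal(seen$bad, 0L)
  expect_lt(median(best), 1e-3)
})

test_that("tdo_minimize is reproducible and never degrades the best", {
  sphere <- benchmark_function("sphere")
  b <- bounds(-5, 5, dim = 3)
  r1 <- tdo_minimize(sphere, b, tdo_config(10, 20, seed = 3))
  r2 <- tdo_minimize(sphere, b, tdo_config(10, 20, seed = 3))
  expect_identical(r1$best_position, r2$best_position)
  expect_identical(r1$trace, r2$trace)

  init <- initialize_population(b, 10, seed = 5, objective = sphere)
  one <- tdo_minimize(sphere, b, tdo_config(10, 1, seed = 5))
  expect_lte(one$best_fitness, min(init$fitness))

  expect_error(tdo_config(pop_size = 1), "pop_size")
})

test_that("greedy monotonicity holds on a rugged objective", {
  rast <- benchmark_function("rastrigin")
  res <- tdo_minimize(rast, bounds(-5, 5, dim = 4),
                      tdo_config(8, 40, seed = 11))
  expect_true(all(diff(res$trace) <= 1e-12))
  expect_equal(res$best_fitness, utils::tail(res$trace, 1))
})
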