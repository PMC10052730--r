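test_that("leader weights enforce ordering and unit sum", {
  w <- leader_weights(0.5, 0.3, 0.2)
  expect_equal(sum(w$w), 1)
  expect_error(leader_weights(0.3, 0.3, 0.4), "weights")
  expect_error(leader_weights(0.6, 0.3, 0.2), "sum to 1")
  expect_error(leader_weights(0.2, 0.5, 0.3), "weights")
})

test_that("two-stage convergence coefficient matches its schedule", {
  expect_equal(convergence_coefficient(0, 100), 1.8)
  expect_equal(convergence_coefficient(100, 100), 0)
  # branch values around the stage switch at T/2
  expect_equal(convergence_coefficient(49, 100), 0.918)
  expect_equal(convergence_coefficient(50, 100), 1.2)
  expect_gt(convergence_coefficient(50, 100),
            convergence_coefficient(49, 100))  # upward jump
  expect_error(convergence_coefficient(101, 100), "out of range")
  for (T_max in c(10, 37, 200)) {
    h <- convergence_coefficient(0:T_max, T_max)
    expect_true(all(h >= 0 & h <= 1.8))
  }
})

test_that("noise schedule interpolates its endpoints and strictly
           decreases", {
  expect_equal(noise_sigma(0, 50, 0.1, 0.001), 0.1)
  expect_equal(noise_sigma(50, 50, 0.1, 0.001), 0.001)
  for (prm in list(c(1, 0), c(0.5, 1e-4), c(2, 0.5))) {
    s <- noise_sigma(0:100, 100, prm[1], prm[2])
    expect_true(all(diff(s) < 0))
  }
  expect_error(noise_sigma(0, 10, 0.1, 0.1), "sigma0 > sigma_min")
})

test_that("prey estimate is the weighted leader sum plus noise", {
  w <- leader_weights(0.5, 0.3, 0.2)
  p <- c(1.5, -2)
  expect_equal(estimate_prey(p, p, p, w, sigma_t = 0), p)
  # 0.5*1 + 0.3*2 + 0.2*3 = 1.7
  expect_equal(estimate_prey(1, 2, 3, w, sigma_t = 0), 1.7)
  expect_equal(estimate_prey(1, 2, 3, w, noise = 0.1), 1.8)
  expect_error(estimate_prey(1, c(1, 2), 1, w), "shape")
  expect_error(estimate_prey(1, 2, 3, weights = list(w = c(1, 0, 0))),
               "weights")
})

test_that("position update follows the prey and stays within bounds", {
  b <- bounds(-5, 5, dim = 1)
  expect_equal(update_position(3, 3, h = 1.5, b, r = 0.2), 3)
  # r = 1 so R = h = 1: 0 - 1 * (0 - 1) = 1
  expect_equal(update_position(1, 0, h = 1, b, r = 1), 1)
  b3 <- bounds(c(-1, 0, -2), c(1, 2, 0))
  set.seed(42)
  for (i in 1:200) {
    x <- runif(3, b3$lower, b3$upper)
    prey <- runif(3, b3$lower - 1, b3$upper + 1)  # possibly out of box
    out <- update_position(x, prey, h = runif(1, 0, 1.8), b3)
    expect_true(all(out >= b3$lower - 1e-12 & out <= b3$upper + 1e-12))
  }
})

test_that("sine-cosine blend hits its endpoint identities", {
  M1 <- c(1, 2); M2 <- c(3, 4); M3 <- c(5, 6)
  expect_equal(sine_cosine_position(M1, M2, M3, 0), M3)
  expect_equal(sine_cosine_position(M1, M2, M3, pi / 2), M1)
  expect_equal(sine_cosine_position(1, 1, 1, pi / 4),
               sqrt(2) / 2 + 0.5 + sqrt(2) / 2)
  expect_error(sine_cosine_position(1, c(1, 2), 1, 0), "shape")
  expect_error(sine_cosine_position(1, 1, 1, pi), "theta")
})

test_that("igwo and gwo runs are reproducible with non-increasing traces", {
  sphere <- benchmark_function("sphere")
  b <- bounds(-5, 5, dim = 4)
  cfg <- igwo_config(10, 40, seed = 8)
  r1 <- igwo_minimize(sphere, b, cfg)
  r2 <- igwo_minimize(sphere, b, cfg)
  expect_identical(r1$best_position, r2$best_position)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace) <= 1e-12))
  g1 <- gwo_minimize(sphere, b, cfg)
  g2 <- gwo_minimize(sphere, b, cfg)
  expect_identical(g1$best_position, g2$best_position)
  expect_true(all(diff(g1$trace) <= 1e-12))
  expect_false(identical(r1$best_position, g1$best_position))
  expect_error(igwo_config(pop_size = 2), "pop_size")
})

test_that("igwo converges on a smoke-test sphere", {
  sphere <- benchmark_function("sphere")
  best <- sapply(1:5, function(s) {
    igwo_minimize(sphere, bounds(-5, 5, dim = 5),
                  igwo_config(20, 100, seed = s))$best_fitness
  })
  expect_lt(median(best), 1e-3)
})
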