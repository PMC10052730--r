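test_that("parameter count matches the layer-by-layer hand count", {
  # d=8, F=2, J=3, H=4, C=4: conv 2*3+2=8; BN 4; pooled floor(6/2)=3;
  # FC 4*(2*3)+4=28; output 4*4+4=20; total 60
  spec <- network_spec(8, filters = 2, kernel = 3, hidden = 4, classes = 4)
  expect_equal(parameter_count(spec), 60L)
  expect_error(network_spec(8, filters = 0), "filters")
  expect_error(network_spec(4, kernel = 5), "kernel")
  # doubling H adds H*(F*pooled) + H + C*H parameters
  spec2 <- network_spec(8, filters = 2, kernel = 3, hidden = 8, classes = 4)
  expect_equal(parameter_count(spec2) - parameter_count(spec),
               4L * (2L * 3L) + 4L + 4L * 4L)
})

test_that("flatten/unflatten round-trips random parameter vectors", {
  spec <- network_spec(10, filters = 3, kernel = 4, hidden = 5, classes = 3)
  set.seed(2)
  for (i in 1:5) {
    theta <- rnorm(parameter_count(spec))
    layers <- respwolf:::unflatten_params(theta, spec)
    expect_equal(respwolf:::flatten_params(layers, spec), theta)
  }
  expect_error(respwolf:::unflatten_params(rnorm(10), spec), "shape")
})

test_that("zero parameters give exactly uniform probabilities", {
  spec <- network_spec(8, filters = 2, kernel = 3, hidden = 4, classes = 4)
  theta <- numeric(parameter_count(spec))
  X <- matrix(rnorm(40), nrow = 5)
  p <- dcnn_forward(theta, spec, X)
  expect_equal(p, matrix(0.25, 5, 4), tolerance = 1e-12)
})

test_that("probabilities are normalized for random parameters", {
  spec <- network_spec(9, filters = 3, kernel = 3, hidden = 4, classes = 3)
  set.seed(5)
  for (i in 1:10) {
    theta <- runif(parameter_count(spec), -3, 3)
    p <- dcnn_forward(theta, spec, matrix(rnorm(27), nrow = 3))
    expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1))  # saturation to 0/1 is fp-legal
  }
})

test_that("single-path network matches a hand computation", {
  # d=4, F=1, J=3 -> conv positions (x1..x3), (x2..x4); H=1, C=2.
  # Stats mean 0 / var 1 - 1e-5 make the BN denominator exactly 1.
  spec <- network_spec(4, filters = 1, kernel = 3, hidden = 1, classes = 2)
  expect_equal(parameter_count(spec), 12L)
  theta <- c(0, 0, 1,      # conv weights: picks x3 then x4
             0,            # conv bias
             1, 0,         # BN scale, shift
             1, 0,         # FC weight, bias
             0.5, -0.25,   # output weights
             0, 1)         # output biases
  ns <- list(mean = 0, var = 1 - 1e-5)
  x <- c(1, 2, 3, 4)
  # conv -> (3, 4); BN identity; ReLU -> (3, 4); max-pool -> 4;
  # hidden ReLU(4) = 4; logits (2, 0); SoftMax
  p <- dcnn_forward(theta, spec, x, ns)
  expect_equal(as.numeric(p), c(exp(2), 1) / (exp(2) + 1),
               tolerance = 1e-12)
})

test_that("cross-entropy matches closed forms and stays non-negative", {
  spec <- network_spec(8, filters = 2, kernel = 3, hidden = 4, classes = 4)
  theta <- numeric(parameter_count(spec))  # uniform model
  X <- matrix(rnorm(32), nrow = 4)
  y <- factor(c("a", "b", "c", "d"))
  expect_equal(cross_entropy_loss(theta, spec, X, y), log(4),
               tolerance = 1e-9)
  set.seed(7)
  for (i in 1:5) {
    th <- runif(parameter_count(spec), -3, 3)
    expect_gte(cross_entropy_loss(th, spec, X, y,
                                  conv_batch_stats(th, spec, X)), 0)
  }
  expect_error(cross_entropy_loss(theta, spec, X, y,
                                  class_levels = c("a", "b")),
               "label")
})

test_that("training is deterministic, consistent with its objective, and
           degenerate at B = 0", {
  set.seed(31)
  n <- 60
  y <- rep(c("u", "v"), each = n / 2)
  X <- cbind(ifelse(y == "u", -2, 2) + rnorm(n, sd = 0.4),
             rnorm(n), rnorm(n), rnorm(n))
  spec <- network_spec(4, filters = 2, kernel = 3, hidden = 3, classes = 2)
  cfg <- igwo_config(10, 30, seed = 5)
  m1 <- train_with_igwo(spec, X, y, config = cfg)
  m2 <- train_with_igwo(spec, X, y, config = cfg)
  expect_identical(m1$parameters, m2$parameters)
  # best fitness re-evaluates to the loss of the stored parameters
  expect_equal(m1$result$best_fitness,
               cross_entropy_loss(m1$parameters, spec, X, y,
                                  m1$norm_stats, m1$classes),
               tolerance = 1e-9)
  m0 <- train_with_igwo(spec, X, y, config = cfg, param_bound = 0)
  expect_true(all(m0$parameters == 0))
  expect_equal(unname(predict(m0, X, type = "prob")[1, ]), c(0.5, 0.5))
  expect_error(train_with_igwo(spec, X, rep("u", n), config = cfg),
               "two classes")
})

test_that("prediction breaks ties toward the lowest class index and
           round-trips through JSON", {
  spec <- network_spec(4, filters = 1, kernel = 3, hidden = 2, classes = 3)
  model <- structure(list(spec = spec,
                          parameters = numeric(parameter_count(spec)),
                          classes = c("a", "b", "c"),
                          norm_stats = list(mean = 0, var = 1),
                          param_bound = 0, result = NULL),
                     class = "igwo_dcnn")
  X <- matrix(rnorm(8), nrow = 2)
  expect_equal(predict(model, X), c("a", "a"))  # uniform -> first class
  expect_identical(predict(model, X), predict(model, X))
  m2 <- dcnn_from_json(dcnn_to_json(model))
  expect_equal(m2$parameters, model$parameters)
  expect_equal(predict(m2, X), predict(model, X))
  expect_error(predict(model, matrix(0, 2, 7)), "shape")
})
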