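# Parameter encoding, forward pass, prediction, backpropagation.

test_that("parameter count follows fan_in*fan_out + fan_out per layer pair", {
  expect_equal(param_count(network_spec(c(1, 1, 1))), 4)
  expect_equal(param_count(network_spec(c(2, 3, 1))), 13)
  expect_equal(param_count(network_spec(c(8, 8, 2))),
               (8 * 8) + 8 + (8 * 2) + 2)
  expect_equal(param_count(network_spec(c(4, 5, 6, 2))),
               4 * 5 + 5 + 5 * 6 + 6 + 6 * 2 + 2)
})

test_that("encode/decode round-trips exactly and checks lengths", {
  spec <- network_spec(c(8, 8, 2))
  v <- seq_len(param_count(spec)) / 10
  expect_identical(encode_params(decode_params(v, spec)), v)
  set.seed(4)
  r <- stats::rnorm(param_count(spec))
  expect_identical(encode_params(decode_params(r, spec)), r)

  z <- decode_params(rep(0, param_count(spec)), spec)
  expect_true(all(vapply(unclass(z), function(l) all(l$w == 0) && all(l$b == 0),
                         logical(1))))
  expect_error(decode_params(rep(0, 93), spec), "expected.*94|dimension",
               ignore.case = TRUE)

  # documented order: layer-1 weights row-major by source node, then biases
  spec2 <- network_spec(c(2, 2, 2))
  p <- decode_params(1:12, spec2)
  expect_equal(p[[1]]$w, matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(p[[1]]$b, c(5, 6))
  expect_equal(p[[2]]$b, c(11, 12))
})

test_that("forward pass matches scalar hand evaluation", {
  # zero parameters: every sigmoid output is 0.5
  spec <- network_spec(c(8, 8, 2))
  z <- decode_params(rep(0, param_count(spec)), spec)
  out <- nn_forward(z, spec, matrix(stats::runif(24), 3, 8))
  expect_true(all(out == 0.5))

  # hand-computed 2-2-2 example
  spec2 <- network_spec(c(2, 2, 2))
  flat <- c(0.1, -0.2, 0.3, 0.4, 0.05, -0.05,   # layer 1: w (row-major), b
            0.5, -0.5, 0.25, 0.75, 0.2, -0.1)   # layer 2
  p <- decode_params(flat, spec2)
  x <- c(0.6, -1.2)
  sg <- function(z) 1 / (1 + exp(-z))
  h1 <- sg(0.1 * 0.6 + 0.3 * (-1.2) + 0.05)
  h2 <- sg(-0.2 * 0.6 + 0.4 * (-1.2) - 0.05)
  o1 <- sg(0.5 * h1 + 0.25 * h2 + 0.2)
  o2 <- sg(-0.5 * h1 + 0.75 * h2 - 0.1)
  out2 <- nn_forward(p, spec2, matrix(x, 1, 2))
  expect_equal(as.vector(out2), c(o1, o2), tolerance = 1e-12)

  expect_error(nn_forward(p, spec2, matrix(1, 1, 3)), "dimension")
  expect_error(nn_forward(p, spec2, matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("forward pass is permutation-equivariant over rows", {
  spec <- network_spec(c(8, 8, 2))
  set.seed(2)
  p <- decode_params(stats::rnorm(param_count(spec)), spec)
  X <- matrix(stats::runif(80), 10, 8)
  perm <- sample.int(10)
  expect_equal(nn_forward(p, spec, X)[perm, ], nn_forward(p, spec, X[perm, ]))
})

test_that("prediction takes the larger output node, ties to class 0", {
  spec <- network_spec(c(2, 2, 2))
  # weights chosen so output node activations are controlled by input sign
  sg <- function(z) 1 / (1 + exp(-z))
  flat <- c(rep(0, 6), 5, -5, 0, 0, 0, 0)  # out1 = sg(5*h1), out2 = sg(-5*h1)
  p <- decode_params(flat, spec)
  out <- nn_forward(p, spec, matrix(c(1, 1), 1, 2))
  expect_equal(out[1], sg(5 * 0.5))
  expect_identical(nn_predict(p, spec, matrix(c(1, 1), 1, 2)), 0L)

  # zero network ties at (0.5, 0.5) -> label 0
  z <- decode_params(rep(0, 12), spec)
  expect_identical(nn_predict(z, spec, matrix(1, 1, 2)), 0L)

  # score is the class-1 node
  expect_equal(nn_score(p, spec, matrix(c(1, 1), 1, 2)), sg(-5 * 0.5))
})

test_that("one hand-derived gradient step on a 1-1-1 network", {
  spec <- network_spec(c(1, 1, 1))
  w1 <- 0.8; b1 <- -0.1; w2 <- 1.4; b2 <- 0.3
  x <- 0.5; y <- 1
  p <- decode_params(c(w1, b1, w2, b2), spec)
  sg <- function(z) 1 / (1 + exp(-z))
  z1 <- w1 * x + b1; h <- sg(z1)
  z2 <- w2 * h + b2; yhat <- sg(z2)
  # loss (single sample) = 0.5 * (yhat - y)^2
  d2 <- (yhat - y) * yhat * (1 - yhat)
  d1 <- d2 * w2 * h * (1 - h)
  lr <- 0.25
  expected <- c(w1 - lr * d1 * x, b1 - lr * d1,
                w2 - lr * d2 * h, b2 - lr * d2)
  trained <- backprop_train(p, spec, matrix(x, 1, 1), matrix(y, 1, 1),
                            train_config(learning_rate = lr, epochs = 1))
  expect_equal(encode_params(trained), expected, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  spec <- network_spec(c(4, 3, 2))
  d <- param_count(spec)
  for (s in 1:20) {
    set.seed(s)
    flat <- stats::rnorm(d, sd = 0.8)
    X <- matrix(stats::rnorm(5 * 4), 5, 4)
    Y <- one_hot(stats::rbinom(5, 1, 0.5))
    g <- nn_gradient(flat, spec, X, Y)
    h <- 1e-6
    fd <- vapply(seq_len(d), function(k) {
      up <- flat; up[k] <- up[k] + h
      dn <- flat; dn[k] <- dn[k] - h
      (nn_gradient(up, spec, X, Y)$loss - nn_gradient(dn, spec, X, Y)$loss) / (2 * h)
    }, numeric(1))
    denom <- pmax(abs(fd), 1e-8)
    expect_lt(max(abs(g$grad - fd) / denom), 1e-4)
  }
})

test_that("training loss is non-increasing on a fixed batch at lr 0.01", {
  spec <- network_spec(c(8, 8, 2))
  set.seed(7)
  p <- decode_params(stats::runif(param_count(spec), -1, 1), spec)
  X <- matrix(stats::runif(32 * 8), 32, 8)
  y <- stats::rbinom(32, 1, 0.4)
  trained <- backprop_train(p, spec, X, one_hot(y),
                            train_config(learning_rate = 0.01, epochs = 200))
  hist <- attr(trained, "loss_history")
  expect_gte(length(hist), 2)
  expect_true(all(diff(hist) <= 1e-12))
})

test_that("degenerate training configs behave as documented", {
  spec <- network_spec(c(2, 2, 2))
  p <- decode_params(stats::rnorm(12), spec)
  out <- backprop_train(p, spec, matrix(1, 4, 2), one_hot(c(0, 1, 0, 1)),
                        train_config(epochs = 0))
  expect_equal(encode_params(out), encode_params(p))
})

test_that("models round-trip through the text serialization", {
  task <- make_task(3, n = 120, effect = 2)
  model <- train_irsa_bp(task$train, network_spec(),
                         irsa_config(max_iter = 2, seed = 1),
                         train_config(epochs = 5),
                         normalization = task$norm)
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(encode_params(back$params), encode_params(model$params),
               tolerance = 1e-12)
  expect_equal(back$spec$layer_sizes, model$spec$layer_sizes)
  expect_equal(unname(back$normalization$x_min),
               unname(model$normalization$x_min), tolerance = 1e-12)
  # predictions survive the round trip
  X <- task$test$features
  expect_identical(nn_predict(back$params, back$spec, X),
                   nn_predict(model$params, model$spec, X))
})
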