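test_that("multiplicative weight update follows the closed form", {
  expect_equal(update_spiking_weights(0.5, e = 1, lr = 0.1), 0.45)
  W <- matrix(runif(12, 0.01, 0.09), 3, 4)
  expect_identical(update_spiking_weights(W, e = 0, lr = 0.35), W)  # fixed point
  expect_equal(update_spiking_weights(0, e = 2, lr = 0.1), 0)  # silenced stays silenced
  expect_error(update_spiking_weights(W, e = NaN, lr = 0.1), "finite")
  expect_error(update_spiking_weights(W, e = 1, lr = 0), "positive")
})

test_that("multiplicative updates preserve sign when |lr * e| < 1", {
  set.seed(41)
  for (rep in 1:50) {
    w <- runif(1, -1, 1)
    lr <- runif(1, 0.01, 0.9)
    e <- runif(1, -0.99, 0.99) / lr
    expect_equal(sign(update_spiking_weights(w, e, lr)), sign(w))
  }
  expect_warning(out <- update_spiking_weights(0.5, e = 20, lr = 0.1), "clamped")
  expect_gt(out, 0)
})

test_that("decoder error signal matches its closed form", {
  expect_equal(decoder_error_signal(1, 0.5), 0.125)
  expect_equal(decoder_error_signal(0.3, 0.3), 0)
  expect_equal(decoder_error_signal(0, 0.5), -0.125)
})

test_that("decoder backprop equals the analytic gradient step to 1e-12", {
  set.seed(43)
  for (rep in 1:5) {
    net <- decoder_net(6, 2, seed = rep)
    x <- rpois(6, 5)
    y <- runif(1)
    lr <- 0.15
    upd <- decoder_backprop(net, x, y, lr)
    ref <- ref_decoder_gradstep(net, x, y, lr)
    expect_equal(upd$W1, ref$W1, tolerance = 1e-12)
    expect_equal(upd$b1, ref$b1, tolerance = 1e-12)
    expect_equal(upd$w2, ref$w2, tolerance = 1e-12)
    expect_equal(upd$b2, ref$b2, tolerance = 1e-12)
  }
})

test_that("zero error leaves the whole model bit-identical", {
  net <- decoder_net(6, 2, seed = 5)
  x <- c(2, 3, 1, 0, 4, 2)
  y_fix <- decoder_forward(net, x)$y
  upd <- decoder_backprop(net, x, y_fix)  # target equals output
  expect_identical(upd$W1, net$W1)
  expect_identical(upd$w2, net$w2)
  W <- matrix(0.05, 2, 2)
  expect_identical(update_spiking_weights(W, 0, 0.1), W)
})

test_that("repeated updates on one pair drive the output error monotonically down", {
  net <- decoder_net(6, 2, seed = 8)
  x <- c(5, 3, 6, 2, 4, 5)
  y <- 0.8
  errs <- numeric(40)
  for (i in 1:40) {
    net <- decoder_backprop(net, x, y, lr = 0.05)
    errs[i] <- abs(y - decoder_forward(net, x)$y)
  }
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[40], errs[1])
})

test_that("kernel traces follow the causal exponential closed form", {
  expect_equal(kernel_trace(numeric(0), 50), 0)
  expect_equal(kernel_trace(10, t = 25, tau = 10), exp(-15 / 10))
  expect_equal(kernel_trace(c(10, 20), t = 25, tau = 10),
               exp(-1.5) + exp(-0.5))
  expect_equal(kernel_trace(30, t = 25), 0)  # future spikes do not count
  # weight increment: zero trace gives zero, and it is linear in lambda
  expect_equal(kernel_weight_update(0, e = 2, lambda = 0.1), 0)
  expect_equal(kernel_weight_update(1.5, 0.5, 0.2),
               2 * kernel_weight_update(1.5, 0.5, 0.1))
})

test_that("learning-rate container validates its defaults", {
  lr <- learning_rates()
  expect_equal(lr$lr_mf_grc, 0.1)
  expect_equal(lr$lr_grc_pc, 0.35)
  expect_equal(lr$lr_decoder, 0.15)
  expect_error(learning_rates(lr_mf_grc = 0), "positive")
})
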