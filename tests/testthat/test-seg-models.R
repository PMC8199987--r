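test_that("latent-code shape follows the layer arithmetic", {
  full <- network_spec(base_filters = 16, depth = 4)
  ls <- latent_shape(full, c(224L, 224L, 224L))
  expect_identical(ls$spatial, c(14L, 14L, 14L))
  expect_identical(ls$channels, 128L)
  small <- network_spec(base_filters = 4, depth = 2)
  ls2 <- latent_shape(small, c(32L, 32L, 32L))
  expect_identical(ls2$spatial, c(8L, 8L, 8L))
  expect_identical(ls2$channels, 8L)
  expect_error(latent_shape(full, c(100L, 100L, 100L)), "divisible")
})

test_that("encode obeys the shape chain and is deterministic", {
  m <- build_model(tiny_spec(), seed = 4)
  X <- array(runif(16^3), c(16, 16, 16))
  Z1 <- encode(m, X)
  Z2 <- encode(m, X)
  expect_identical(Z1, Z2)
  expect_identical(dim(Z1), c(4L, 4L, 4L, 4L))
  # zero input with zero biases gives a zero latent code
  Z0 <- encode(m, array(0, c(16, 16, 16)))
  expect_true(all(Z0 == 0))
  expect_error(encode(m, array(0, c(15, 15, 15))), "divisible")
})

test_that("skip connections change only decoder conv input channels", {
  spec_u <- network_spec(base_filters = 4, depth = 3, skip_connections = TRUE)
  spec_s <- network_spec(base_filters = 4, depth = 3, skip_connections = FALSE)
  mu <- build_model(spec_u, seed = 1)
  ms <- build_model(spec_s, seed = 1)
  # expected extra weights: k^3 * skip_channels * out_channels per dec block
  k <- spec_u$kernel_size; z <- spec_u$base_filters
  extra <- sum(sapply(1:3, function(j) k^3 * (z * 2^(j - 1)) * (z * 2^(j - 1))))
  expect_equal(n_params(mu) - n_params(ms), extra)
  # encoders identical under the same seed
  expect_identical(mu$params$enc, ms$params$enc)
})

test_that("segmentation probabilities are normalized and reproducible", {
  m <- build_model(tiny_spec(), seed = 9)
  X <- mini_prep()[[1]]$image
  p1 <- segment(m, X)
  expect_lt(max(abs(apply(p1, 1:3, sum) - 1)), 1e-6)
  m2 <- build_model(tiny_spec(), seed = 9)
  expect_identical(p1, segment(m2, X))
  expect_identical(dim(p1)[1:3], dim(X))
})

test_that("analytic gradients match finite differences", {
  # tiny volume so central differences are cheap; checks the whole backprop
  set.seed(50)
  spec <- network_spec(base_filters = 2, depth = 1, num_classes = 3)
  m <- build_model(spec, seed = 2)
  X <- array(runif(4^3), c(4, 4, 4))
  lab <- array(sample(0:2, 64, replace = TRUE), c(4, 4, 4))
  fb <- segrecon:::seg_forward_backward(m, X, lab)
  loss_at <- function(model) segrecon:::seg_forward_backward(model, X, lab)$loss
  eps <- 1e-6
  for (probe in list(c("enc", 1L), c("dec", 1L))) {
    W <- m$params[[probe[1]]][[as.integer(probe[2])]]$W
    for (idx in c(1L, length(W) %/% 2L, length(W))) {
      mp <- m; mp$params[[probe[1]]][[as.integer(probe[2])]]$W[idx] <- W[idx] + eps
      mm <- m; mm$params[[probe[1]]][[as.integer(probe[2])]]$W[idx] <- W[idx] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      ana <- fb$grads[[probe[1]]][[as.integer(probe[2])]]$W[idx]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss, is seeded, and beats an untrained model", {
  prep <- mini_prep()[1:4]
  m0 <- build_model(tiny_spec(), seed = 21)
  cfg <- train_config(epochs = 30, learning_rate = 5e-3, seed = 22)
  m1 <- train_segmentation(m0, prep, cfg)
  expect_lt(tail(m1$trace, 1), m1$trace[1])
  m1b <- train_segmentation(m0, prep, cfg)
  expect_identical(m1$trace, m1b$trace)
  expect_identical(m1$params, m1b$params)
  expect_gt(mean(model_dice(m1, prep)), mean(model_dice(m0, prep)))
  # shape mismatch across the cohort fails loudly
  odd <- prep
  odd[[2]]$image <- array(0, c(20, 20, 20))
  expect_error(train_segmentation(m0, odd, cfg), "shape")
})

test_that("a model overfit to one phantom segments it accurately", {
  s <- mini_prep()[[1]]
  m <- build_model(network_spec(base_filters = 4, depth = 2), seed = 33)
  m <- train_segmentation(m, list(s), train_config(epochs = 1200,
                                                   learning_rate = 5e-3,
                                                   seed = 34))
  pred <- label_map(segment(m, s$image))
  for (cl in 1:3) expect_gt(dice(pred, s$labels, cl), 0.8)
})

test_that("checkpoints round-trip the spec, seed and parameters", {
  m <- build_model(tiny_spec(), seed = 77)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$spec, m$spec)
  expect_identical(back$seed, m$seed)
  expect_identical(back$params, m$params)
  unlink(path)
})
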