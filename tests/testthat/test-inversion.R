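test_that("inversion decoder mirrors the encoder and is seed-stable", {
  spec <- network_spec(base_filters = 4, depth = 2)
  d1 <- build_inversion_decoder(spec, seed = 5)
  d2 <- build_inversion_decoder(spec, seed = 5)
  expect_identical(d1$params, d2$params)
  Z <- array(0, c(8, 8, 8, 8))
  out <- reconstruct(d1, Z)
  expect_identical(dim(out), c(32L, 32L, 32L))
  expect_identical(reconstruct(d1, Z), out)
  expect_error(reconstruct(d1, array(0, c(8, 8, 8, 4))), "channels")
})

test_that("an identity encoder is inverted to near-zero error", {
  enc <- linear_encoder(matrix(1, 1, 1))
  set.seed(61)
  imgs <- lapply(1:4, function(i) array(runif(8^3), c(8, 8, 8)))
  dec <- build_inversion_decoder(enc$spec, latent_channels = 1L,
                                 out_channels = 1L, depth = 0L, seed = 6)
  cfg <- train_config(epochs = 300, learning_rate = 1e-2, seed = 7,
                      loss_name = "mse", val_fraction = 0, patience = 1000L)
  dec <- train_inversion_decoder(enc, imgs, cfg, decoder = dec)
  mse <- mean(vapply(imgs, function(X)
    mean((reconstruct(dec, encode(enc, X)) - X)^2), 0))
  expect_lt(mse, 1e-4)
})

test_that("training never touches the frozen encoder", {
  prep <- mini_prep()
  m <- build_model(tiny_spec(), seed = 41)
  before <- m$params$enc
  att <- run_attack(m, prep[1:2], prep[3:6],
                    train_config(epochs = 3, seed = 42, loss_name = "mse"))
  expect_identical(m$params$enc, before)
  expect_length(att$reconstructions, 2)
  expect_identical(dim(att$reconstructions[[1]]), dim(prep[[1]]$image))
})

test_that("the leakage guard rejects overlapping cohorts", {
  prep <- mini_prep()
  m <- build_model(tiny_spec(), seed = 43)
  expect_error(run_attack(m, prep[1:2], prep[2:5],
                          train_config(epochs = 2, seed = 1)),
               "leakage")
})

test_that("reconstruction error is consistent with the training objective", {
  prep <- mini_prep()
  m <- build_model(tiny_spec(), seed = 44)
  imgs <- lapply(prep[3:6], `[[`, "image")
  cfg <- train_config(epochs = 20, learning_rate = 1e-3, seed = 45,
                      loss_name = "mse", val_fraction = 0, patience = 100L)
  dec <- train_inversion_decoder(m, imgs, cfg)
  final <- tail(dec$trace$train, 1)
  per_img <- vapply(imgs, function(X)
    mean((reconstruct(dec, encode(m, X)) - X)^2), 0)
  expect_lt(mean(per_img), 2 * final)
})

test_that("attack success improves with attacker-cohort size (majority of seeds)", {
  prep <- mini_prep()
  # an untrained (random, frozen) encoder suffices for the data-volume effect;
  # attack cohorts of 3 vs 5 subjects from the 6-phantom fixture pool
  wins <- 0L
  for (seed in 1:3) {
    m <- build_model(tiny_spec(), seed = 50 + seed)
    imgs <- lapply(prep, `[[`, "image")
    cfg <- function(s) train_config(epochs = 15, learning_rate = 1e-3,
                                    seed = s, loss_name = "mse",
                                    val_fraction = 0, patience = 100L)
    probe <- preprocess_subject(generate_phantom(fast_params(), 999 + seed),
                                divisor = 4L)$image
    mse_for <- function(k) {
      dec <- train_inversion_decoder(m, imgs[seq_len(k)], cfg(60 + seed))
      mean((reconstruct(dec, encode(m, probe)) - probe)^2)
    }
    if (mse_for(5) <= mse_for(3)) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
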