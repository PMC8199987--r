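test_that("apply_field warps with the stated convention", {
  # displacing sampling coords by +1 voxel in x shifts content backwards
  x <- array(0, c(8, 8, 8))
  x[4, 4, 4] <- 1
  one <- array(1, dim(x))
  f <- displacement_field(one, one * 0, one * 0)
  w <- apply_field(x, f)
  expect_equal(w[3, 4, 4], 1)
})

test_that("self-registration returns an essentially zero field", {
  X <- mini_prep()[[1]]$image
  reg <- register(X, X, iters = 20)
  expect_true(reg$converged)
  expect_lt(mean_displacement_norm(reg$field), 0.1)
})

test_that("registration output has coherent structure", {
  prep <- mini_prep()
  reg <- register(prep[[1]]$image, prep[[2]]$image, iters = 15)
  expect_s3_class(reg$field, "displacement_field")
  expect_identical(dim(reg$field$x), dim(prep[[1]]$image))
  expect_true(all(is.finite(reg$field$x)))
  expect_true(is.finite(reg$mi))
  expect_named(reg$diagnostics, c("err_affine", "err_final"))
})
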