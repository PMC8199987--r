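# The direct convolution kernels are the package's computational core; check
# them against the independent im2col/gemm formulation and adjoint identities.

test_that("direct convolution matches the im2col reference path", {
  set.seed(9)
  x <- array(rnorm(12^3 * 3), c(12, 12, 12, 3))
  W <- array(rnorm(27 * 3 * 5), c(3, 3, 3, 3, 5))
  b <- rnorm(5)
  y <- segrecon:::conv3_fwd(x, W, b)
  cols <- segrecon:::im2col3(x, 3L)
  yref <- sweep(cols %*% matrix(W, ncol = 5), 2, b, "+")
  dim(yref) <- dim(y)
  expect_equal(y, yref, tolerance = 1e-12)

  gy <- array(rnorm(length(y)), dim(y))
  gx <- segrecon:::conv3_bwd_x(gy, W, dim(x))
  gxref <- segrecon:::col2im3(matrix(gy, ncol = 5) %*% t(matrix(W, ncol = 5)),
                              dim(x), 3L)
  expect_equal(gx, gxref, tolerance = 1e-12)

  gw <- segrecon:::conv3_bwd_w(x, gy, 3L)
  gwref <- crossprod(cols, matrix(gy, ncol = 5))
  expect_equal(as.vector(gw$gW), as.vector(gwref), tolerance = 1e-10)
  expect_equal(gw$gb, colSums(matrix(gy, ncol = 5)), tolerance = 1e-12)
})

test_that("pooling and upsampling are exact adjoint pairs", {
  set.seed(10)
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  pl <- segrecon:::maxpool3(x)
  expect_identical(dim(pl$out), c(4L, 4L, 4L, 2L))
  # every pooled value is the max of its block
  expect_true(all(pl$out >= x[pl$idx]))
  expect_equal(pl$out, array(x[pl$idx], dim(pl$out)))
  # <grad, up(x)> == <down(grad), x> for the nearest-upsampling adjoint
  u <- segrecon:::upsample3(x)
  g <- array(rnorm(length(u)), dim(u))
  lhs <- sum(g * u)
  rhs <- sum(segrecon:::upsample3_bwd(g) * x)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # max-pool backward routes gradient to the argmax voxels only
  gp <- array(rnorm(length(pl$out)), dim(pl$out))
  gx <- segrecon:::maxpool3_bwd(gp, pl$idx, dim(x))
  expect_equal(sum(gx != 0), length(unique(pl$idx)))
  expect_equal(sum(gx), sum(gp), tolerance = 1e-12)
})

test_that("separable smoothing preserves constants and mass structure", {
  x <- array(1, c(10, 10, 10))
  s <- segrecon:::smooth_gaussian(x, 2)
  expect_equal(as.vector(s), rep(1, 1000), tolerance = 1e-12)
  # a delta spreads symmetrically
  d <- array(0, c(11, 11, 11)); d[6, 6, 6] <- 1
  sd3 <- segrecon:::sepconv3(d, segrecon:::gauss_kernel(1))
  expect_equal(sd3[5, 6, 6], sd3[7, 6, 6])
  expect_equal(sd3[6, 5, 6], sd3[6, 7, 6])
  expect_equal(sum(sd3), 1, tolerance = 1e-12)
})
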