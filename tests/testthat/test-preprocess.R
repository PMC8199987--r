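test_that("padding reaches network-compatible sizes", {
  x <- array(runif(181 * 217 * 181), c(181, 217, 181))
  pv <- pad_to_divisible(x, 16, target = c(224, 224, 224))
  expect_identical(dim(pv$data), c(224L, 224L, 224L))
  expect_identical(crop_to_original(pv), x)
  pv2 <- pad_to_divisible(x, 16)
  expect_identical(dim(pv2$data), c(192L, 224L, 192L))
  y <- array(1, c(32, 32, 32))
  pv3 <- pad_to_divisible(y, 16)
  expect_identical(pv3$data, y)
  expect_identical(pv3$original_extent$offset, c(0L, 0L, 0L))
  expect_error(pad_to_divisible(y, 16, target = c(16, 16, 16)), "smaller")
})

test_that("pad/crop is an exact identity for arbitrary shapes", {
  set.seed(401)
  for (rep in 1:5) {
    d <- sample(5:40, 3, replace = TRUE)
    x <- array(rnorm(prod(d)), d)
    div <- sample(c(2, 4, 8, 16), 1)
    pv <- pad_to_divisible(x, div)
    expect_true(all(dim(pv$data) %% div == 0))
    expect_identical(crop_to_original(pv), x)
    # padding splits evenly, extra voxel trailing
    lo <- pv$original_extent$offset
    hi <- dim(pv$data) - d - lo
    expect_true(all((hi - lo) %in% c(0L, 1L)))
  }
})

test_that("bias correction recovers the generator's known field", {
  p <- phantom_params(noise_sigma = 0, bias_amplitude = 0.3)
  for (seed in c(31, 7, 99)) {
    s <- generate_phantom(p, seed)
    m <- brain_mask(s)
    corrected <- correct_bias_field(s$image, m)
    # residual field: estimated over true, up to the overall gain
    r <- attr(corrected, "bias_field")[m] / s$true_bias[m]
    r <- r / mean(r)
    expect_lt(max(abs(r - 1)), 0.1)
    # the corrected image is closer to the unbiased truth than the input
    means <- c(0, unname(p$class_means[1:4]))
    unbiased <- array(means[s$labels + 1L], dim(s$labels))
    expect_lt(mean(abs(corrected[m] / unbiased[m] - 1)),
              mean(abs(s$image[m] / unbiased[m] - 1)))
    # mean intensity inside the mask is preserved
    expect_equal(mean(corrected[m]), mean(s$image[m]), tolerance = 1e-10)
  }
})

test_that("bias correction is near-neutral without bias and exact on constants", {
  p <- phantom_params(noise_sigma = 0, bias_amplitude = 0)
  s <- generate_phantom(p, 13)
  m <- brain_mask(s)
  corrected <- correct_bias_field(s$image, m)
  expect_lt(max(abs(corrected[m] - s$image[m]) / s$image[m]), 0.01)
  const <- array(2, c(16, 16, 16))
  cc <- correct_bias_field(const, array(TRUE, dim(const)))
  expect_equal(as.vector(cc), rep(2, length(const)), tolerance = 1e-12)
  expect_error(correct_bias_field(const, array(FALSE, dim(const))), "empty mask")
})

test_that("intensity normalization is a robust affine-invariant rescale", {
  s <- generate_phantom(fast_params(), 3)
  m <- brain_mask(s)
  nrm <- normalize_intensity(s$image, m)
  expect_gte(min(nrm), 0)
  expect_lte(max(nrm), 1)
  # invariance under positive affine intensity transforms
  nrm2 <- normalize_intensity(3.7 * s$image + 11, m)
  expect_equal(nrm, nrm2, tolerance = 1e-12)
  # direct recomputation of the percentile mapping
  q <- quantile(s$image[m], c(0.01, 0.99), names = FALSE)
  manual <- pmin(pmax((s$image - q[1]) / (q[2] - q[1]), 0), 1)
  expect_equal(nrm, manual)
  expect_error(normalize_intensity(array(1, dim(m)), m), "constant")
})

test_that("label fusion performs an exact voxel-wise lookup", {
  set.seed(77)
  lab <- array(sample(c(0L, 10L, 11L, 20L, 30L), 64, replace = TRUE), c(4, 4, 4))
  lut <- c("10" = 1L, "11" = 1L, "20" = 2L, "30" = 3L, "0" = 0L)
  fused <- fuse_labels(lab, lut)
  for (v in seq_along(lab))
    expect_identical(fused[v], unname(lut[as.character(lab[v])]))
  expect_setequal(unique(as.vector(fused)), intersect(0:3, fused))
  # voxel counts preserved per fused class
  expect_identical(sum(fused == 1L), sum(lab %in% c(10L, 11L)))
  # identity lut
  idlut <- setNames(0:3, as.character(0:3))
  small <- array(sample(0:3, 27, replace = TRUE), c(3, 3, 3))
  expect_identical(fuse_labels(small, idlut), small)
  # unmapped label named in the error
  bad <- small; bad[1] <- 99L
  expect_error(fuse_labels(bad, idlut), "99")
})
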