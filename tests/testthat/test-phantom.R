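test_that("phantom generation is seeded and subject-specific", {
  p <- fast_params()
  s1 <- generate_phantom(p, 42)
  s1b <- generate_phantom(p, 42)
  s2 <- generate_phantom(p, 43)
  expect_identical(s1, s1b)
  expect_lt(ssim(s1$image, s2$image), 1)
  expect_false(identical(s1$image, s2$image))
})

test_that("labels partition the brain and classes are non-empty", {
  for (seed in c(1, 9, 77)) {
    s <- generate_phantom(fast_params(), seed)
    expect_true(all(s$labels %in% 0:4))
    counts <- tabulate(s$labels[s$labels > 0], nbins = 4)
    expect_true(all(counts[1:3] > 0))
    # brain mask is exactly the union of classes 1-3 (disjoint by encoding)
    expect_identical(brain_mask(s), s$labels %in% 1:3 & array(TRUE, dim(s$labels)))
  }
  sk <- generate_phantom(phantom_params(grid_size = 24, with_skull = TRUE), 5)
  expect_gt(sum(sk$labels == 4L), 0)
})

test_that("noise-free bias-free phantoms are exactly piecewise constant", {
  p <- fast_params(noise_sigma = 0, bias_amplitude = 0)
  s <- generate_phantom(p, 7)
  for (cl in 1:3) {
    v <- s$image[s$labels == cl]
    expect_equal(var(v), 0)
    expect_equal(mean(v), unname(p$class_means[cl]))
  }
  expect_true(all(s$image[s$labels == 0L] == 0))
})

test_that("the bias field respects its amplitude bound inside the brain", {
  p <- fast_params(noise_sigma = 0, bias_amplitude = 0.3)
  s <- generate_phantom(p, 11)
  means <- c(0, unname(p$class_means[1:4]))
  unbiased <- array(means[s$labels + 1L], dim(s$labels))
  m <- brain_mask(s)
  ratio <- s$image[m] / unbiased[m]
  expect_true(all(ratio >= 1 - 0.3 - 1e-12))
  expect_true(all(ratio <= 1 + 0.3 + 1e-12))
  expect_equal(s$true_bias[m], ratio, tolerance = 1e-12)
})

test_that("cohorts have unique ids and are reproducible", {
  p <- fast_params()
  coh <- generate_cohort(p, 40, seed = 5)
  ids <- vapply(coh$subjects, `[[`, "", "subject_id")
  expect_length(unique(ids), 40)
  one <- generate_cohort(p, 1, seed = 5)
  expect_length(one$subjects, 1)
  a <- generate_cohort(p, 6, seed = 7)
  b <- generate_cohort(p, 6, seed = 7)
  expect_identical(a, b)
  expect_error(generate_cohort(p, 0), "at least 1")
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(phantom_params(grid_size = 8), "at least 16")
  expect_error(phantom_params(class_means = c(1, 1, 2, 3)), "distinct")
  expect_error(phantom_params(noise_sigma = -1), "non-negative")
  expect_error(phantom_params(bias_amplitude = 1), "bias_amplitude")
})

test_that("NIfTI round trip preserves arrays, spacing and manifest", {
  coh <- generate_cohort(fast_params(), 3, seed = 12)
  dir <- file.path(tempdir(), "cohort-rt")
  mf <- write_cohort(coh, dir)
  expect_length(mf$subject_ids, 3)
  back <- read_cohort(dir)
  for (i in 1:3) {
    expect_identical(back$subjects[[i]]$image, coh$subjects[[i]]$image)
    expect_identical(back$subjects[[i]]$labels, coh$subjects[[i]]$labels)
    expect_equal(back$subjects[[i]]$spacing, c(1, 1, 1))
  }
  expect_identical(cohort_ids <- vapply(back$subjects, `[[`, "", "subject_id"),
                   mf$subject_ids)
  # header spacing directly
  img <- RNifti::readNifti(file.path(dir, "sub-001_image.nii.gz"))
  expect_equal(as.numeric(RNifti::pixdim(img)), c(1, 1, 1))
  unlink(dir, recursive = TRUE)
  expect_error(write_cohort(coh, file.path("/proc/definitely-unwritable", "x")))
})
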