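test_that("SSIM identity, symmetry and shape contracts hold", {
  set.seed(101)
  a <- array(runif(16^3), c(16, 16, 16))
  b <- array(runif(16^3), c(16, 16, 16))
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a))
  expect_error(ssim(a, array(0, c(8, 8, 8))), "shape")
  expect_error(ssim(a, b, data_range = 0), "positive")
})

test_that("SSIM matches the constant-image closed form", {
  z <- array(0, c(12, 12, 12))
  o <- array(1, c(12, 12, 12))
  C1 <- 0.01^2
  expect_equal(ssim(z, o, data_range = 1), C1 / (1 + C1), tolerance = 1e-8)
})

test_that("intensity correlation equals the textbook formula", {
  set.seed(102)
  a <- array(runif(10^3), c(10, 10, 10))
  expect_equal(intensity_correlation(a, a), 1)
  expect_equal(intensity_correlation(a, -a), -1)
  # flattened toy case computed by hand: r = 11 / sqrt(130)
  x <- array(c(1, 2, 3, 4, 1, 2, 3, 4), c(2, 2, 2))
  y <- array(c(2, 4, 5, 9, 2, 4, 5, 9), c(2, 2, 2))
  expect_equal(intensity_correlation(x, y), 11 / sqrt(5 * 26))
  expect_error(intensity_correlation(a, array(1, dim(a))), "constant")
})

test_that("Dice handles identity, disjoint and toy overlap cases", {
  a <- array(0L, c(4, 4, 4))
  b <- a
  a[1:2] <- 1L
  b[2:3] <- 1L
  expect_equal(dice(a, b, 1L), 0.5)   # overlap {2} of sizes 2 and 2
  expect_equal(dice(a, a, 1L), 1)
  d <- array(0L, c(4, 4, 4)); d[10] <- 1L
  e <- array(0L, c(4, 4, 4)); e[20] <- 1L
  expect_equal(dice(d, e, 1L), 0)
  expect_equal(dice(d, e, 7L), 1)     # both empty -> 1 by convention
})

test_that("metric matrices score all pairs with the true pairs on the diagonal", {
  set.seed(103)
  vols <- lapply(1:3, function(i) array(runif(8^3), c(8, 8, 8)))
  names(vols) <- paste0("s", 1:3)
  mm <- metric_matrix(vols, vols, function(a, b) ssim(a, b))
  expect_identical(dim(unclass(mm)), c(3L, 3L))
  expect_equal(unname(diag(mm)), rep(1, 3))
  mm2 <- metric_matrix(vols, vols, function(a, b) ssim(a, b))
  expect_identical(mm, mm2)
  expect_error(metric_matrix(setNames(vols, c("a", "b", "zzz")), vols,
                             function(a, b) 1), "zzz")
})

test_that("identification ranks follow the orientation with worst-tie rule", {
  m <- matrix(c(0.9, 0.1, 0.1,
                0.2, 0.8, 0.1,
                0.3, 0.2, 0.7), 3, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  rs <- rank_true_matches(structure(m, higher_is_better = TRUE,
                                    class = c("metric_matrix", "matrix")))
  expect_identical(unname(rs$ranks), c(1L, 1L, 1L))
  expect_identical(rs$match_count, 3L)
  expect_equal(rs$mean_rank, 1)
  # true score 2nd of 4
  m2 <- matrix(runif(16), 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  m2[2, ] <- c(0.9, 0.8, 0.1, 0.2)
  rs2 <- rank_true_matches(structure(m2, higher_is_better = TRUE,
                                     class = c("metric_matrix", "matrix")))
  expect_identical(unname(rs2$ranks[2]), 2L)
  # all-tied row takes the worst rank
  m3 <- matrix(0.5, 5, 5, dimnames = list(paste0("s", 1:5), paste0("s", 1:5)))
  rs3 <- rank_true_matches(structure(m3, higher_is_better = TRUE,
                                     class = c("metric_matrix", "matrix")))
  expect_true(all(rs3$ranks == 5L))
  # lower-is-better orientation (deformation-style scores)
  m4 <- matrix(c(0.1, 2, 3, 0.5), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  rs4 <- rank_true_matches(structure(m4, higher_is_better = FALSE,
                                     class = c("metric_matrix", "matrix")))
  expect_identical(unname(rs4$ranks), c(1L, 1L))
})

test_that("displacement-norm summaries are exact on constructed fields", {
  z <- array(0, c(6, 6, 6))
  f0 <- displacement_field(z, z, z)
  expect_equal(mean_displacement_norm(f0), 0)
  f1 <- displacement_field(z + 3, z + 4, z)
  expect_equal(mean_displacement_norm(f1), 5)
  uz <- z; uz[1:108] <- 2                 # half the voxels displaced by 2 mm
  f2 <- displacement_field(z, z, uz)
  expect_equal(mean_displacement_norm(f2), 1)
  expect_error(mean_displacement_norm(f2, mask = z > 0), "empty mask")
  bad <- displacement_field(z + NA_real_, z, z)
  expect_error(mean_displacement_norm(bad), "finite")
})

test_that("resegmentation Dice reduces to the model's own Dice on the original", {
  prep <- mini_prep()[1:2]
  m <- build_model(tiny_spec(), seed = 71)
  m <- train_segmentation(m, prep, train_config(epochs = 25,
                                                learning_rate = 5e-3, seed = 72))
  own <- unname(model_dice(m, prep[1]))
  expect_equal(resegmentation_dice(m, prep[[1]]$image, prep[[1]]$labels), own)
  # pure-noise reconstruction degrades the segmentation
  set.seed(73)
  noise <- array(runif(length(prep[[1]]$image)), dim(prep[[1]]$image))
  expect_lt(resegmentation_dice(m, noise, prep[[1]]$labels), own)
})
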