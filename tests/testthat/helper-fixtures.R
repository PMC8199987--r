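# Shared fixtures, generated in code. Small grids (16^3) keep unit tests
# fast; the end-to-end acceptance tests use the full desk-scale 32^3 study.

fast_params <- function(...) {
  args <- modifyList(list(grid_size = 16L, noise_sigma = 0.01,
                          bias_amplitude = 0.1, deform_sigma = 1.0),
                     list(...))
  do.call(phantom_params, args)
}

tiny_spec <- function(skip = TRUE) {
  network_spec(base_filters = 2L, depth = 2L, skip_connections = skip)
}

# memoised preprocessed mini-cohort (grid 16, 6 subjects)
.fixture_env <- new.env()

mini_prep <- function() {
  if (is.null(.fixture_env$prep)) {
    coh <- generate_cohort(fast_params(), 6, seed = 303)
    prep <- lapply(coh$subjects, preprocess_subject, divisor = 4L)
    names(prep) <- vapply(prep, `[[`, "", "subject_id")
    .fixture_env$prep <- prep
  }
  .fixture_env$prep
}

# --- independent brute-force oracles (direct windowed formulas) -------------

ssim_oracle <- function(a, b, data_range = 1, window = 7L) {
  d <- dim(a)
  r <- window %/% 2L
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  acc <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    xi <- max(1L, i - r):min(d[1], i + r)
    yj <- max(1L, j - r):min(d[2], j + r)
    zk <- max(1L, k - r):min(d[3], k + r)
    av <- a[xi, yj, zk]; bv <- b[xi, yj, zk]
    mua <- mean(av); mub <- mean(bv)
    va <- mean(av^2) - mua^2; vb <- mean(bv^2) - mub^2
    cab <- mean(av * bv) - mua * mub
    acc <- acc + ((2 * mua * mub + C1) * (2 * cab + C2)) /
      ((mua^2 + mub^2 + C1) * (max(va, 0) + max(vb, 0) + C2))
  }
  acc / prod(d)
}

corr_oracle <- function(x, y) {
  x <- as.vector(x); y <- as.vector(y)
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

dice_oracle <- function(a, b, cl) {
  ia <- which(a == cl); ib <- which(b == cl)
  if (length(ia) + length(ib) == 0) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}
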