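#' Zero-pad a volume so every dimension is divisible by a given factor
#'
#' Pooling across \code{n} encoder levels requires each spatial dimension to
#' be divisible by \code{pool^n} (e.g. a 181 x 217 x 181 scan is padded to
#' 224^3 for four levels of 2x pooling). Padding is split as evenly as
#' possible per side, with the extra voxel on the trailing side, and the
#' original extent is recorded so the padding can be removed exactly.
#'
#' @param image 3D numeric array.
#' @param divisor Required divisor of every padded dimension.
#' @param target Optional explicit per-axis output size; must be at least the
#'   input size and divisible by \code{divisor}.
#' @param value Fill value for the padding (default 0, the background).
#' @return A \code{padded_volume}: list with \code{data} and
#'   \code{original_extent} (per-axis \code{offset} and \code{size}).
#' @seealso \code{\link{crop_to_original}}
#' @export
pad_to_divisible <- function(image, divisor, target = NULL, value = 0) {
  d <- dim(image)
  stopifnot(length(d) == 3, divisor >= 1)
  if (is.null(target)) {
    target <- as.integer(ceiling(d / divisor) * divisor)
  } else {
    target <- as.integer(target)
    if (length(target) == 1L) target <- rep(target, 3L)
    if (any(target < d)) stop("target size smaller than the input")
    if (any(target %% divisor != 0)) stop("target not divisible by divisor")
  }
  pad <- target - d
  lo <- pad %/% 2L                      # extra voxel goes on the trailing side
  out <- array(value, target)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- image
  structure(list(data = out,
                 original_extent = list(offset = as.integer(lo),
                                        size = as.integer(d))),
            class = "padded_volume")
}

#' Remove the padding recorded by \code{\link{pad_to_divisible}}
#'
#' @param padded A \code{padded_volume}, or any 3D array together with an
#'   \code{extent} taken from one.
#' @param extent Original extent (needed only when \code{padded} is a bare
#'   array).
#' @return The unpadded 3D array, bit-identical to the original input.
#' @export
crop_to_original <- function(padded, extent = NULL) {
  if (inherits(padded, "padded_volume")) {
    extent <- padded$original_extent
    padded <- padded$data
  }
  if (is.null(extent)) stop("extent required when cropping a bare array")
  o <- extent$offset; s <- extent$size
  padded[o[1] + seq_len(s[1]), o[2] + seq_len(s[2]), o[3] + seq_len(s[3])]
}

# Deterministic Lloyd clustering of a vector into k classes, initialised at
# spread quantiles. Returns per-element cluster means.
cluster_means <- function(v, k = 3L, iters = 15L) {
  centers <- unique(quantile(v, probs = seq(0.15, 0.85, length.out = k),
                             names = FALSE))
  if (length(centers) < 2L) return(rep(mean(v), length(v)))
  for (it in seq_len(iters)) {
    assign <- max.col(-abs(outer(v, centers, "-")), ties.method = "first")
    newc <- vapply(seq_along(centers),
                   function(j) if (any(assign == j)) mean(v[assign == j])
                               else centers[j], 0)
    if (max(abs(newc - centers)) < 1e-10) { centers <- newc; break }
    centers <- newc
  }
  assign <- max.col(-abs(outer(v, centers, "-")), ties.method = "first")
  centers[assign]
}

#' Correct a smooth multiplicative bias field
#'
#' Classify-and-correct surrogate for histogram-based corrections such as N3:
#' log-intensities inside the mask are clustered into a few tissue classes,
#' the per-class log-mean is subtracted, and the smooth residual (heavily
#' Gaussian low-passed, mask-weighted so background cannot leak in) is taken
#' as the log bias field and divided out. The estimate is refined over a few
#' passes and the overall gain is fixed so the mean intensity inside the mask
#' is unchanged. On images with no inhomogeneity the residuals vanish and the
#' correction is neutral. The synthetic generator stores the true field it
#' applied, which is how this estimator is validated.
#'
#' @param image 3D numeric array (positive inside the mask).
#' @param mask Logical 3D array; the brain.
#' @param n_classes Number of intensity clusters used to explain anatomy
#'   (default 3 tissue classes).
#' @param fwhm_frac Low-pass scale as a fraction of the smallest image
#'   dimension (default 0.5); larger values remove only coarser fields.
#' @param n_iter Number of estimate-and-divide refinement passes.
#' @return Bias-corrected 3D array, with the estimated field in attribute
#'   \code{"bias_field"}.
#' @export
correct_bias_field <- function(image, mask, n_classes = 3L, fwhm_frac = 0.5,
                               n_iter = 5L) {
  stopifnot(identical(dim(image), dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  sigma <- fwhm_frac * min(dim(image)) / 2.355
  m <- array(as.numeric(mask), dim(image))
  den <- smooth_gaussian(m, sigma)
  eps <- 1e-8
  work <- image
  total_log <- array(0, dim(image))
  for (it in seq_len(n_iter)) {
    logv <- log(pmax(work[mask], eps))
    resid <- array(0, dim(image))
    resid[mask] <- logv - cluster_means(logv, n_classes)
    field_log <- smooth_gaussian(resid * m, sigma) / pmax(den, 1e-6)
    field_log <- field_log - mean(field_log[mask])   # unit-gain field
    total_log <- total_log + field_log
    work <- work / exp(field_log)
  }
  out <- work * (mean(image[mask]) / mean(work[mask]))
  attr(out, "bias_field") <- exp(total_log)
  out
}

#' Robust intensity normalization to [0, 1]
#'
#' Maps the 1st and 99th intensity percentiles inside the mask to 0 and 1 and
#' clips; a monotone, scanner-robust rescaling that makes intensities of
#' different subjects comparable and fixes the SSIM data range at 1.
#'
#' @param image 3D numeric array.
#' @param mask Logical 3D array over which the percentiles are taken.
#' @param probs Lower/upper percentile pair (default \code{c(0.01, 0.99)}).
#' @return Normalized array with all values in [0, 1].
#' @export
normalize_intensity <- function(image, mask, probs = c(0.01, 0.99)) {
  stopifnot(identical(dim(image), dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  q <- quantile(image[mask], probs = probs, names = FALSE, type = 7)
  if (q[2] <= q[1]) stop("image is constant inside the mask")
  out <- (image - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Fuse fine-grained labels into the study's tissue classes
#'
#' Voxel-wise lookup that combines, e.g., many individual gyrus labels into a
#' single gyri class and the deep-grey structures into one class, leaving the
#' classes \code{0:3} (plus optionally 4 for skull) used for training.
#'
#' @param labels 3D integer array.
#' @param lut Named list or vector mapping each original label (name, as a
#'   string of the integer) to its fused class.
#' @return 3D integer array of fused classes.
#' @export
fuse_labels <- function(labels, lut) {
  lut <- unlist(lut)
  present <- sort(unique(as.vector(labels)))
  missing <- setdiff(as.character(present), names(lut))
  if (length(missing) > 0)
    stop("labels without a fusion entry: ", paste(missing, collapse = ", "))
  out <- array(as.integer(lut[as.character(labels)]), dim(labels))
  out
}

#' Standard preprocessing chain for one subject
#'
#' Bias-field correction (when requested), robust normalization to [0, 1] and
#' padding to a pooling-compatible size, with the label volume padded in the
#' same frame. The brain mask is taken from the labels (classes 1-3).
#'
#' @param subject A \code{subject}.
#' @param divisor Required divisibility of the padded dimensions
#'   (\code{pool^depth} of the network to be trained).
#' @param target Optional explicit padded size.
#' @param correct_bias Run \code{\link{correct_bias_field}} first.
#' @param lut Optional label-fusion lookup passed to \code{\link{fuse_labels}}.
#' @return The subject with \code{image} and \code{labels} replaced by their
#'   preprocessed versions and the padding extent stored in \code{extent}.
#' @export
preprocess_subject <- function(subject, divisor, target = NULL,
                               correct_bias = TRUE, lut = NULL) {
  mask <- brain_mask(subject)
  img <- subject$image
  if (correct_bias) img <- correct_bias_field(img, mask)
  img <- normalize_intensity(img, mask)
  lab <- subject$labels
  if (!is.null(lut)) lab <- fuse_labels(lab, lut)
  pimg <- pad_to_divisible(img, divisor, target)
  plab <- pad_to_divisible(lab, divisor, target)
  subject$image <- pimg$data
  labarr <- plab$data
  storage.mode(labarr) <- "integer"
  subject$labels <- labarr
  subject$extent <- pimg$original_extent
  subject
}
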