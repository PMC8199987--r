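#' Structural similarity index (SSIM) between two volumes
#'
#' Windowed similarity of luminance, contrast and structure with the usual
#' stabilization constants \code{C1 = (0.01 * data_range)^2} and
#' \code{C2 = (0.03 * data_range)^2}, averaged over local windows. Local
#' statistics use a cubic uniform window (side \code{window}), normalised at
#' the borders so partial windows use only the voxels they cover. Identical
#' inputs score exactly 1.
#'
#' @param a,b 3D numeric arrays of the same shape.
#' @param data_range Dynamic range of the data (1 after
#'   \code{\link{normalize_intensity}}).
#' @param window Side of the cubic window (odd; default 7).
#' @param mask Optional logical array; the SSIM map is averaged over it
#'   (default: whole volume).
#' @return Scalar in \code{[-1, 1]}.
#' @export
ssim <- function(a, b, data_range = 1, window = 7L, mask = NULL) {
  if (!identical(dim(a), dim(b))) stop("volumes have different shapes")
  if (data_range <= 0) stop("data_range must be positive")
  w <- rep(1, window)
  ones <- array(1, dim(a))
  nn <- sepconv3(ones, w)
  mu_a <- sepconv3(a, w) / nn
  mu_b <- sepconv3(b, w) / nn
  va <- pmax(sepconv3(a * a, w) / nn - mu_a^2, 0)
  vb <- pmax(sepconv3(b * b, w) / nn - mu_b^2, 0)
  cab <- sepconv3(a * b, w) / nn - mu_a * mu_b
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  map <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  if (is.null(mask)) mean(map) else mean(map[mask > 0])
}

#' Intensity correlation between two volumes
#'
#' Pearson correlation of the grey levels inside a mask. This is the score
#' widely reported as "MCC" for reconstruction quality; despite that
#' abbreviation it is a continuous cross-correlation of intensities, not the
#' (binary) Matthews correlation coefficient, and it is implemented here as
#' the former.
#'
#' @param a,b 3D numeric arrays of the same shape.
#' @param mask Optional logical array restricting the support (default:
#'   whole volume).
#' @return Scalar in \code{[-1, 1]}.
#' @export
intensity_correlation <- function(a, b, mask = NULL) {
  if (!identical(dim(a), dim(b))) stop("volumes have different shapes")
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  x <- a[mask > 0]; y <- b[mask > 0]
  if (length(x) < 2) stop("mask must contain at least 2 voxels")
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sum(dx * dx); sy <- sum(dy * dy)
  if (sx == 0 || sy == 0) stop("constant input inside the mask")
  sum(dx * dy) / sqrt(sx * sy)
}

#' Dice overlap of one class between two label maps
#'
#' \eqn{2 |A \cap B| / (|A| + |B|)}; if the class is absent from both maps
#' the score is 1 by convention.
#'
#' @param labels_a,labels_b Integer label arrays of the same shape.
#' @param class_id Class whose overlap is measured.
#' @return Scalar in \code{[0, 1]}.
#' @export
dice <- function(labels_a, labels_b, class_id) {
  if (!identical(dim(labels_a), dim(labels_b))) stop("label maps differ in shape")
  A <- labels_a == class_id
  B <- labels_b == class_id
  sa <- sum(A); sb <- sum(B)
  if (sa + sb == 0) return(1)
  2 * sum(A & B) / (sa + sb)
}

#' Mean Dice over several classes
#' @param labels_a,labels_b Integer label arrays.
#' @param classes Classes to average over.
#' @return Mean of the per-class Dice scores.
#' @export
mean_dice <- function(labels_a, labels_b, classes = 1:3) {
  mean(vapply(classes, function(cl) dice(labels_a, labels_b, cl), 0))
}

#' Dice of a model's segmentation of a reconstruction
#'
#' Segments the reconstructed volume with the originally trained model and
#' scores it against the true subject's ground-truth labels — probing whether
#' reconstructions remain usable for the segmentation task itself.
#'
#' @param model The trained \code{seg_model}.
#' @param reconstruction Reconstructed volume, preprocessed like the training
#'   inputs.
#' @param ground_truth_labels The true subject's label volume.
#' @param classes Classes averaged over (default 1:3).
#' @return Mean Dice.
#' @export
resegmentation_dice <- function(model, reconstruction, ground_truth_labels,
                                classes = 1:3) {
  pred <- label_map(segment(model, reconstruction))
  mean_dice(pred, ground_truth_labels, classes)
}

#' All-pairs metric matrix between reconstructions and originals
#'
#' Rows are reconstructions, columns candidate original images; entry (i, j)
#' scores reconstruction i against original j. The diagonal (shared id) holds
#' the true-pair scores used by \code{\link{rank_true_matches}}.
#'
#' @param reconstructions Named list of volumes (names = subject ids).
#' @param originals Named list of volumes over the same id universe.
#' @param metric Function \code{(a, b) -> scalar}, e.g. \code{\link{ssim}} or
#'   a wrapper fixing its mask.
#' @param higher_is_better Orientation of the metric (\code{FALSE} for, e.g.,
#'   displacement magnitudes).
#' @return A \code{metric_matrix}: the score matrix with the orientation
#'   attached.
#' @export
metric_matrix <- function(reconstructions, originals, metric,
                          higher_is_better = TRUE) {
  rid <- names(reconstructions); oid <- names(originals)
  if (is.null(rid) || is.null(oid)) stop("both lists must be named by subject id")
  missing <- setdiff(rid, oid)
  if (length(missing) > 0)
    stop("reconstruction ids without an original: ", paste(missing, collapse = ", "))
  m <- matrix(NA_real_, length(rid), length(oid), dimnames = list(rid, oid))
  for (i in seq_along(rid))
    for (j in seq_along(oid))
      m[i, j] <- metric(reconstructions[[i]], originals[[j]])
  structure(m, higher_is_better = isTRUE(higher_is_better),
            class = c("metric_matrix", "matrix"))
}

#' Identification ranks of the true originals
#'
#' For each reconstruction (row), the rank of its true original (the
#' same-id column) among all candidates under the metric's orientation;
#' rank 1 means the reconstruction is most similar to its own original, i.e.
#' the subject is re-identified. Ties give the true pair its worst tied
#' position, so identification risk is never over-stated.
#'
#' @param matrix A \code{\link{metric_matrix}} whose row ids all appear among
#'   its columns.
#' @return A \code{rank_summary}: per-row ranks, \code{match_count} (rank-1
#'   rows), \code{mean_rank}, and the rank histogram.
#' @export
rank_true_matches <- function(matrix) {
  hib <- attr(matrix, "higher_is_better")
  if (is.null(hib)) hib <- TRUE
  rid <- rownames(matrix); oid <- colnames(matrix)
  ranks <- vapply(seq_along(rid), function(i) {
    row <- matrix[i, ]
    true <- row[[rid[i]]]
    others <- row[setdiff(oid, rid[i])]
    if (hib) sum(others > true) + sum(others == true) + 1L
    else sum(others < true) + sum(others == true) + 1L
  }, 0L)
  names(ranks) <- rid
  structure(list(ranks = ranks,
                 match_count = sum(ranks == 1L),
                 mean_rank = mean(ranks),
                 histogram = table(factor(ranks, levels = seq_len(ncol(matrix))))),
            class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  cat(sprintf("Identification: %d/%d correct matches, mean rank %.2f\n",
              x$match_count, length(x$ranks), x$mean_rank))
  invisible(x)
}
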