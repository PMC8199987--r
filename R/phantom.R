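#' Parameters of the synthetic head-phantom generator
#'
#' Describes the population of 3D head phantoms used in place of a real MRI
#' cohort. Each phantom is a smoothly deformed ellipsoidal "brain" carrying a
#' folded cortical ribbon (class 1), deep-grey blobs (class 2) and remaining
#' brain tissue (class 3), optionally wrapped in a bright skull/scalp shell
#' (class 4). The image is the piecewise-constant class-mean map modulated by
#' a smooth multiplicative bias field, plus additive Gaussian noise.
#'
#' @param grid_size Voxels per axis (isotropic volume), at least 16.
#' @param class_means Named numeric vector of intensity means (arbitrary
#'   units) for classes \code{gyri}, \code{deep_grey}, \code{rest} and
#'   \code{skull}; all pairwise distinct. Background is 0.
#' @param noise_sigma SD of additive Gaussian noise (intensity units).
#' @param bias_amplitude Peak relative deviation of the multiplicative bias
#'   field; the field lies in \code{[1 - b, 1 + b]}. Must be in \code{[0, 1)}.
#' @param deform_sigma SD, in voxels, of each component of the smooth random
#'   warp that gives every subject its own anatomy.
#' @param with_skull Add the bright skull/scalp shell (class 4) so that the
#'   brain occupies a smaller fraction of the imaged head.
#' @return An object of class \code{phantom_params}.
#' @export
phantom_params <- function(grid_size = 32L,
                           class_means = c(gyri = 0.55, deep_grey = 0.40,
                                           rest = 0.85, skull = 1.15),
                           noise_sigma = 0.02,
                           bias_amplitude = 0.20,
                           deform_sigma = 1.5,
                           with_skull = FALSE) {
  grid_size <- as.integer(grid_size)
  class_means <- unlist(class_means)
  if (grid_size < 16L) stop("grid_size must be at least 16")
  if (length(class_means) < 4L)
    stop("class_means must give means for gyri, deep_grey, rest and skull")
  if (anyDuplicated(class_means[1:4])) stop("class_means must be pairwise distinct")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop("bias_amplitude must lie in [0, 1)")
  if (deform_sigma < 0) stop("deform_sigma must be non-negative")
  structure(list(grid_size = grid_size, class_means = class_means,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 deform_sigma = deform_sigma, with_skull = isTRUE(with_skull)),
            class = "phantom_params")
}

# Smooth random vector field with per-component SD `sigma_vox` voxels,
# obtained by Gaussian-smoothing white noise and rescaling. Returns a list of
# three grid arrays (displacement in voxels).
random_warp_field <- function(grid, sigma_vox, smooth_sigma) {
  lapply(1:3, function(i) {
    f <- smooth_gaussian(array(rnorm(grid^3), c(grid, grid, grid)), smooth_sigma)
    s <- sd(as.vector(f))
    if (s > 0 && sigma_vox > 0) f * (sigma_vox / s) else f * 0
  })
}

#' Generate one synthetic head phantom
#'
#' The template anatomy is defined by closed-form fields of the voxel
#' coordinates (an ellipsoidal radius for the brain surface, a sinusoidally
#' modulated distance-to-surface band for the gyral ribbon, Gaussian bumps
#' for the deep grey nuclei). Subject identity comes from evaluating those
#' fields at coordinates displaced by a subject-specific smooth random warp,
#' so all subjects share anatomy but are mutually distinguishable.
#'
#' @param params A \code{\link{phantom_params}} object.
#' @param subject_seed Integer seed fixing this subject's warp, bias field and
#'   noise; the same seed reproduces the subject bit-exactly.
#' @param subject_id Identifier stored in the subject (defaults to the seed).
#' @return An object of class \code{subject}: a list with \code{subject_id},
#'   \code{image} (3D numeric array), \code{labels} (3D integer array with
#'   classes 0 background, 1 gyri, 2 deep grey, 3 remaining brain tissue,
#'   4 skull/scalp when enabled), \code{spacing} (mm per voxel) and
#'   \code{true_bias}, the bias field actually applied (useful for validating
#'   bias-field correction).
#' @export
generate_phantom <- function(params, subject_seed,
                             subject_id = paste0("sub-", subject_seed)) {
  stopifnot(inherits(params, "phantom_params"))
  g <- params$grid_size
  with_seed(subject_seed, function() {
    warp <- random_warp_field(g, params$deform_sigma, smooth_sigma = g / 8)
    cx <- (g + 1) / 2
    ax <- c(0.38, 0.32, 0.34) * g
    co <- array(seq_len(g), c(g, g, g))
    X <- co + warp[[1]]
    Y <- aperm(co, c(2, 1, 3)) + warp[[2]]
    Z <- aperm(co, c(3, 2, 1)) + warp[[3]]

    rho <- sqrt(((X - cx) / ax[1])^2 + ((Y - cx) / ax[2])^2 + ((Z - cx) / ax[3])^2)
    dist_surf <- 1 - rho                     # > 0 inside the brain
    omega <- 2 * pi * 3 / g                  # three fold periods across the head
    modulation <- sin(omega * X) * sin(omega * Y) * sin(omega * Z)
    ribbon <- 0.22 * (1 + 0.6 * modulation)  # spatially varying ribbon depth

    blob_centres <- rbind(cx + c(-0.13, 0.05, 0) * g,
                          cx + c(0.13, 0.05, 0) * g,
                          cx + c(0, -0.12, 0.05) * g)
    blob <- array(FALSE, c(g, g, g))
    for (i in seq_len(nrow(blob_centres))) {
      b <- blob_centres[i, ]
      r2 <- ((X - b[1])^2 + (Y - b[2])^2 + (Z - b[3])^2) / (0.09 * g)^2
      blob <- blob | (r2 < 1)
    }

    brain <- dist_surf > 0
    labels <- array(0L, c(g, g, g))
    labels[brain] <- 3L
    labels[brain & blob] <- 2L
    labels[brain & (dist_surf < ribbon)] <- 1L
    if (params$with_skull) labels[rho > 1.05 & rho <= 1.20] <- 4L

    counts <- tabulate(labels[labels > 0L], nbins = 4L)
    if (any(counts[1:3] == 0L))
      stop("grid too small: tissue classes 1-3 are not all represented")

    means <- c(0, unname(params$class_means[1:4]))  # index = class + 1
    unbiased <- array(means[labels + 1L], c(g, g, g))

    bias <- array(1, c(g, g, g))
    if (params$bias_amplitude > 0) {
      f <- smooth_gaussian(array(rnorm(g^3), c(g, g, g)), g / 4)
      f <- f / max(abs(f))
      bias <- 1 + params$bias_amplitude * f
    }
    image <- unbiased * bias
    if (params$noise_sigma > 0)
      image <- image + array(rnorm(g^3, sd = params$noise_sigma), c(g, g, g))

    structure(list(subject_id = subject_id, image = image, labels = labels,
                   spacing = c(1, 1, 1), true_bias = bias,
                   seed = as.integer(subject_seed)),
              class = "subject")
  })
}

#' Generate a cohort of phantoms
#'
#' Subject seeds are derived deterministically from the master seed, so the
#' whole cohort is reproducible from \code{(params, n, seed)}.
#'
#' @param params A \code{\link{phantom_params}} object.
#' @param n Number of subjects (default 40, a typical public brain-MRI
#'   database size).
#' @param seed Master integer seed.
#' @return An object of class \code{cohort}: list of subjects plus the seed
#'   and parameters that produced them.
#' @export
generate_cohort <- function(params, n = 40L, seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be at least 1")
  subjects <- lapply(seq_len(n), function(i) {
    generate_phantom(params, derive_seed(seed, i),
                     subject_id = sprintf("sub-%03d", i))
  })
  structure(list(subjects = subjects, seed = as.integer(seed), params = params),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  g <- x$params$grid_size
  cat(sprintf("Synthetic cohort: %d subjects, %d^3 voxels, seed %d%s\n",
              length(x$subjects), g, x$seed,
              if (x$params$with_skull) ", with skull" else ", skull-stripped"))
  invisible(x)
}

cohort_ids <- function(cohort) vapply(cohort$subjects, `[[`, "", "subject_id")

#' Write a cohort to NIfTI files plus a JSON manifest
#'
#' One image and one label volume per subject (\code{<id>_image.nii.gz},
#' \code{<id>_labels.nii.gz}) with 1 mm isotropic spacing in the header, and a
#' \code{manifest.json} recording ids, per-subject seeds and the generator
#' parameters. \code{\link{read_cohort}} reproduces the arrays and spacing
#' exactly.
#'
#' @param cohort A \code{cohort}.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  probe <- file.path(directory, ".write-test")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("directory not writable: ", directory)
  unlink(probe)
  for (s in cohort$subjects) {
    img <- RNifti::asNifti(s$image, pixdim = s$spacing)
    lab <- RNifti::asNifti(s$labels, pixdim = s$spacing)
    RNifti::writeNifti(img, file.path(directory, paste0(s$subject_id, "_image.nii.gz")))
    RNifti::writeNifti(lab, file.path(directory, paste0(s$subject_id, "_labels.nii.gz")))
  }
  manifest <- list(
    subject_ids = cohort_ids(cohort),
    subject_seeds = vapply(cohort$subjects, `[[`, 1L, "seed"),
    seed = cohort$seed,
    spacing = cohort$subjects[[1]]$spacing,
    params = unclass(cohort$params))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by \code{\link{write_cohort}}
#'
#' @param directory Directory containing the NIfTI files and manifest.
#' @return A \code{cohort} object.
#' @export
read_cohort <- function(directory) {
  mf <- jsonlite::read_json(file.path(directory, "manifest.json"),
                            simplifyVector = TRUE)
  subjects <- lapply(seq_along(mf$subject_ids), function(i) {
    id <- mf$subject_ids[i]
    img <- RNifti::readNifti(file.path(directory, paste0(id, "_image.nii.gz")))
    lab <- RNifti::readNifti(file.path(directory, paste0(id, "_labels.nii.gz")))
    spacing <- as.numeric(RNifti::pixdim(img))
    imgarr <- array(as.numeric(img), dim(img))       # plain arrays, header
    labarr <- array(as.integer(lab), dim(lab))       # attributes stripped
    structure(list(subject_id = id, image = imgarr,
                   labels = labarr, spacing = spacing,
                   true_bias = NULL, seed = as.integer(mf$subject_seeds[i])),
              class = "subject")
  })
  params <- do.call(phantom_params, mf$params[c("grid_size", "class_means",
                                               "noise_sigma", "bias_amplitude",
                                               "deform_sigma", "with_skull")])
  structure(list(subjects = subjects, seed = as.integer(mf$seed), params = params),
            class = "cohort")
}

#' Brain mask of a subject (labelled tissue, classes 1-3)
#' @param subject A \code{subject}.
#' @return Logical 3D array.
#' @export
brain_mask <- function(subject) {
  subject$labels >= 1L & subject$labels <= 3L
}
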