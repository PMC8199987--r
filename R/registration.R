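# Two-phase intensity-based registration: a global affine stage driven by
# mutual information, then a dense diffusion-regularised demons refinement.
# The displacement field returned covers only the non-linear stage, so its
# magnitude measures residual shape difference after global alignment.

coord_grids <- function(d) {
  co <- array(seq_len(d[1]), d)
  list(x = co,
       y = aperm(array(seq_len(d[2]), d[c(2, 1, 3)]), c(2, 1, 3)),
       z = aperm(array(seq_len(d[3]), d[c(3, 2, 1)]), c(3, 2, 1)))
}

# Mutual information of two equally shaped volumes from a bins x bins joint
# histogram over their joint intensity range.
mutual_information <- function(a, b, bins = 32L) {
  ra <- range(a); rb <- range(b)
  if (ra[2] == ra[1] || rb[2] == rb[1]) return(0)
  ia <- pmin(as.integer((a - ra[1]) / (ra[2] - ra[1]) * bins) + 1L, bins)
  ib <- pmin(as.integer((b - rb[1]) / (rb[2] - rb[1]) * bins) + 1L, bins)
  joint <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins) / length(a)
  pj <- matrix(joint, bins, bins)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (px[row(pj)[nz]] * py[col(pj)[nz]])))
}

# Rotation matrix from Euler angles (radians), Rz %*% Ry %*% Rx.
rot_matrix <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Resample `moving` on the fixed grid under theta = (t, angles, log-scale):
# moving coords = s * R (x - c) + c + t.
affine_resample <- function(moving, grids, theta) {
  d <- dim(moving)
  cx <- (d + 1) / 2
  R <- rot_matrix(theta[4:6]) * exp(theta[7])
  X <- grids$x - cx[1]; Y <- grids$y - cx[2]; Z <- grids$z - cx[3]
  mx <- R[1, 1] * X + R[1, 2] * Y + R[1, 3] * Z + cx[1] + theta[1]
  my <- R[2, 1] * X + R[2, 2] * Y + R[2, 3] * Z + cx[2] + theta[2]
  mz <- R[3, 1] * X + R[3, 2] * Y + R[3, 3] * Z + cx[3] + theta[3]
  out <- sample3(moving, mx, my, mz, 0L, 0)
  dim(out) <- d
  out
}

affine_stage <- function(moving, fixed, grids, bins = 32L, maxit = 200L) {
  nmi <- function(theta) -mutual_information(affine_resample(moving, grids, theta),
                                             fixed, bins)
  # coarse integer translation search for capture range, then simplex refine
  shifts <- as.matrix(expand.grid(x = c(-4, -2, 0, 2, 4),
                                  y = c(-4, -2, 0, 2, 4),
                                  z = c(-4, -2, 0, 2, 4)))
  vals <- apply(shifts, 1, function(s) nmi(c(s, 0, 0, 0, 0)))
  init <- c(shifts[which.min(vals), ], 0, 0, 0, 0)
  # simplex restarts: re-seeding the simplex at the current optimum refines
  # parameters well past the first collapse of the simplex
  opt <- optim(init, nmi, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-8))
  for (r in 1:2) {
    opt2 <- optim(opt$par, nmi, method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-8,
                                 parscale = c(rep(0.5, 3), rep(0.02, 3), 0.02)))
    if (opt2$value < opt$value) opt <- opt2
  }
  list(theta = opt$par, mi = -opt$value)
}

# Demons refinement with fluid-like regularisation: the per-iteration update
# (not the accumulated field) is Gaussian-smoothed before being added, plus a
# very light elastic smoothing of the total field. Smoothing the total field
# every iteration would compound into a huge effective kernel and shrink any
# genuine deformation towards zero.
demons_stage <- function(moving, fixed, iters = 40L, smooth_sigma = 1.0,
                         elastic_sigma = 0.5, step_cap = 1.0,
                         u0 = NULL) {
  d <- dim(fixed)
  grids <- coord_grids(d)
  g <- grad3(fixed)
  gmag2 <- g$x^2 + g$y^2 + g$z^2
  if (is.null(u0)) {
    ux <- uy <- uz <- array(0, d)
  } else {
    ux <- u0$x; uy <- u0$y; uz <- u0$z
  }
  err0 <- mean((moving - fixed)^2)
  for (it in seq_len(iters)) {
    w <- sample3(moving, grids$x + ux, grids$y + uy, grids$z + uz, 0L, 0)
    dim(w) <- d
    diff <- w - fixed
    denom <- gmag2 + diff^2
    denom[denom < 1e-9] <- 1e-9
    f <- -diff / denom
    dx <- smooth_gaussian(pmin(pmax(f * g$x, -step_cap), step_cap), smooth_sigma)
    dy <- smooth_gaussian(pmin(pmax(f * g$y, -step_cap), step_cap), smooth_sigma)
    dz <- smooth_gaussian(pmin(pmax(f * g$z, -step_cap), step_cap), smooth_sigma)
    ux <- ux + dx; uy <- uy + dy; uz <- uz + dz
    if (it %% 10L == 0L && elastic_sigma > 0) {
      ux <- smooth_gaussian(ux, elastic_sigma)
      uy <- smooth_gaussian(uy, elastic_sigma)
      uz <- smooth_gaussian(uz, elastic_sigma)
    }
  }
  w <- sample3(moving, grids$x + ux, grids$y + uy, grids$z + uz, 0L, 0)
  dim(w) <- d
  list(ux = ux, uy = uy, uz = uz, warped = w,
       err_initial = err0, err_final = mean((w - fixed)^2))
}

downsample2 <- function(x) {
  d <- dim(x)
  h <- d %/% 2L
  co <- coord_grids(h)
  out <- sample3(x, 2 * co$x - 0.5, 2 * co$y - 0.5, 2 * co$z - 0.5, 0L, 0)
  dim(out) <- h
  out
}

upsample_field2 <- function(u, d) {
  co <- coord_grids(d)
  out <- 2 * sample3(u, (co$x + 0.5) / 2, (co$y + 0.5) / 2, (co$z + 0.5) / 2, 0L, 0)
  dim(out) <- d
  out
}

#' Register one volume to another
#'
#' Two phases following common deformable-registration practice: (1) a global
#' affine stage (translation, rotation, isotropic scale) maximizing mutual
#' information, seeded by a coarse translation search; (2) a multi-resolution
#' diffusion-regularised demons refinement producing a dense, smooth
#' displacement field on intensity-comparable (normalised) images. The affine
#' component is deliberately excluded from the returned field: the field's
#' magnitude measures residual, truly non-linear shape difference.
#'
#' @param moving Volume to deform.
#' @param fixed Reference volume of the same shape.
#' @param spacing Voxel spacing in mm (isotropic assumed per axis).
#' @param iters Demons iterations at the full resolution (half as many at the
#'   coarse level).
#' @param smooth_sigma Gaussian regularisation SD (voxels) applied to the
#'   field each iteration.
#' @param bins Histogram bins for mutual information.
#' @return A \code{registration}: \code{aligned} volume, \code{field}
#'   (a \code{displacement_field}), \code{affine} parameters, and
#'   \code{converged} (\code{FALSE}, with diagnostics retained, when the
#'   non-linear stage failed to reduce the mismatch).
#' @export
register <- function(moving, fixed, spacing = c(1, 1, 1), iters = 60L,
                     smooth_sigma = 1.0, bins = 32L) {
  if (!identical(dim(moving), dim(fixed))) stop("volumes have different shapes")
  d <- dim(fixed)
  grids <- coord_grids(d)
  aff <- affine_stage(moving, fixed, grids, bins)
  maff <- affine_resample(moving, grids, aff$theta)

  # coarse-to-fine demons on the affinely aligned pair
  dm_c <- demons_stage(downsample2(maff), downsample2(fixed),
                       iters = max(1L, iters %/% 2L),
                       smooth_sigma = smooth_sigma)
  u0 <- list(x = upsample_field2(dm_c$ux, d),
             y = upsample_field2(dm_c$uy, d),
             z = upsample_field2(dm_c$uz, d))
  dm <- demons_stage(maff, fixed, iters = iters, smooth_sigma = smooth_sigma,
                     u0 = u0)
  field <- structure(list(x = dm$ux, y = dm$uy, z = dm$uz, spacing = spacing),
                     class = "displacement_field")
  structure(list(aligned = dm$warped, field = field, affine = aff$theta,
                 mi = aff$mi, converged = dm$err_final <= dm$err_initial + 1e-12,
                 diagnostics = c(err_affine = dm$err_initial,
                                 err_final = dm$err_final)),
            class = "registration")
}

#' Mean displacement-vector norm of a field
#'
#' Mean Euclidean norm, in mm, of the dense displacement vectors over the
#' mask — the deformation-based reconstruction score: the smaller the norm,
#' the closer the two shapes after global alignment.
#'
#' @param field A \code{displacement_field} from \code{\link{register}}.
#' @param mask Optional logical array (default: whole domain).
#' @return Mean norm in mm.
#' @export
mean_displacement_norm <- function(field, mask = NULL) {
  stopifnot(inherits(field, "displacement_field"))
  if (any(!is.finite(field$x)) || any(!is.finite(field$y)) ||
      any(!is.finite(field$z))) stop("displacement field contains non-finite values")
  nrm <- sqrt((field$x * field$spacing[1])^2 +
              (field$y * field$spacing[2])^2 +
              (field$z * field$spacing[3])^2)
  if (is.null(mask)) return(mean(nrm))
  if (!any(mask > 0)) stop("empty mask")
  mean(nrm[mask > 0])
}

#' Deformation-based similarity of a reconstruction to a candidate original
#'
#' Registers the reconstruction to the candidate and returns the mean
#' displacement norm of the non-linear field (smaller = more similar).
#'
#' @param reconstruction,original Volumes of a common shape.
#' @param mask Optional mask for the norm average.
#' @param ... Passed to \code{\link{register}}.
#' @return Mean displacement norm in mm.
#' @export
deformation_score <- function(reconstruction, original, mask = NULL, ...) {
  reg <- register(reconstruction, original, ...)
  mean_displacement_norm(reg$field, mask)
}

#' Apply a displacement field to a volume
#'
#' Samples \code{volume} at \code{x + u(x)} with trilinear interpolation —
#' used both to warp images and to build ground-truth test deformations.
#'
#' @param volume 3D array.
#' @param field A \code{displacement_field} (displacements in voxels).
#' @return Warped 3D array.
#' @export
apply_field <- function(volume, field) {
  d <- dim(volume)
  grids <- coord_grids(d)
  out <- sample3(volume, grids$x + field$x, grids$y + field$y,
                 grids$z + field$z, 0L, 0)
  dim(out) <- d
  out
}

#' Construct a displacement field object
#' @param x,y,z Per-axis displacement arrays (voxels).
#' @param spacing Voxel spacing in mm.
#' @return A \code{displacement_field}.
#' @export
displacement_field <- function(x, y, z, spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(x), dim(y)), identical(dim(x), dim(z)))
  structure(list(x = x, y = y, z = z, spacing = spacing),
            class = "displacement_field")
}
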