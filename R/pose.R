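#' Pose parameterization of an anchoring plane
#'
#' A human-friendly alternative to raw anchoring vectors: a plane is given by
#' its center (atlas voxels), a dorsoventral tilt angle, a mediolateral tilt
#' angle (both degrees, relative to the standard coronal orientation) and
#' horizontal/vertical scale factors relative to the default coronal plane
#' extents.
#'
#' Angle convention (declared, since tilts admit several sign conventions):
#' the dorsoventral angle tilts the top of the image toward anterior when
#' positive, i.e. the plane normal's sagittal-plane projection makes exactly
#' `dv_angle` degrees with the coronal normal; the mediolateral angle tilts
#' the image-right edge toward anterior when positive, the normal's
#' horizontal-plane projection making exactly `ml_angle` degrees with the
#' coronal normal. Negate either angle to match the opposite convention.
#'
#' @param center Numeric 3-vector, plane midpoint in atlas voxels.
#' @param dv_angle,ml_angle Tilt angles in degrees, each in (-90, 90).
#' @param width_scale,height_scale Positive scale factors; 1 means the plane
#'   spans the full default coronal extents (`Nx` horizontally, `Nz`
#'   vertically).
#' @return An object of class `pose`.
#' @export
pose <- function(center, dv_angle = 0, ml_angle = 0,
                 width_scale = 1, height_scale = 1) {
  if (!is_number3(center)) stop("pose center must be a finite 3-vector", call. = FALSE)
  if (abs(dv_angle) >= 90 || abs(ml_angle) >= 90) {
    stop("pose angles must lie in (-90, 90) degrees", call. = FALSE)
  }
  if (width_scale <= 0 || height_scale <= 0) {
    stop("pose scales must be positive", call. = FALSE)
  }
  structure(list(center = as.numeric(center),
                 dv_angle = as.numeric(dv_angle),
                 ml_angle = as.numeric(ml_angle),
                 width_scale = as.numeric(width_scale),
                 height_scale = as.numeric(height_scale)),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> center=(%s) dv=%g ml=%g scales=(%g, %g)\n",
              paste(signif(x$center, 6), collapse = ", "),
              x$dv_angle, x$ml_angle, x$width_scale, x$height_scale))
  invisible(x)
}

#' Convert a pose to anchoring vectors
#'
#' At `dv = ml = 0`, scales 1 and center on the mid-coronal axis this yields
#' the default coronal anchoring `o = (0, y0, Nz)`, `u = (Nx, 0, 0)`,
#' `v = (0, 0, -Nz)`: image left is the subject's left, image top is
#' superior, with screen y growing downward.
#'
#' @param p A [pose()].
#' @param atlas_dims Integer 3-vector `(Nx, Ny, Nz)`, atlas grid dimensions
#'   in voxels.
#' @return An [anchoring()].
#' @export
pose_to_anchoring <- function(p, atlas_dims) {
  stopifnot(inherits(p, "pose"))
  d <- check_atlas_dims(atlas_dims)
  dv <- p$dv_angle * pi / 180
  ml <- p$ml_angle * pi / 180
  td <- tan(dv); tm <- tan(ml)
  cm <- cos(ml); sm <- sin(ml)
  uhat <- c(cm, sm, 0)
  # plane normal proportional to (-tan(ml), 1, -tan(dv)): its projections
  # onto the horizontal and sagittal planes recover ml and dv exactly
  vdir <- c(td * sm, -td * cm, -tm * sm - cm)
  vhat <- vdir / sqrt(sum(vdir^2))
  u <- d[1] * p$width_scale * uhat
  v <- d[3] * p$height_scale * vhat
  o <- p$center - u / 2 - v / 2
  anchoring(o, u, v)
}

#' Recover a pose from anchoring vectors
#'
#' Exact inverse of [pose_to_anchoring()] for planes expressible in the pose
#' convention (in particular `u` horizontal). Planes tilted 90 degrees or
#' more from coronal (normal with no anterior component) are an error.
#'
#' @param a An [anchoring()].
#' @inheritParams pose_to_anchoring
#' @return A [pose()].
#' @export
anchoring_to_pose <- function(a, atlas_dims) {
  stopifnot(inherits(a, "anchoring"))
  d <- check_atlas_dims(atlas_dims)
  n <- cross3(a$u, a$v)
  if (n[2] <= 0) {
    stop("plane is tilted 90 degrees or more from coronal; pose undefined",
         call. = FALSE)
  }
  ml <- atan(-n[1] / n[2]) * 180 / pi
  dv <- atan(-n[3] / n[2]) * 180 / pi
  pose(center = a$o + (a$u + a$v) / 2,
       dv_angle = dv, ml_angle = ml,
       width_scale = sqrt(sum(a$u^2)) / d[1],
       height_scale = sqrt(sum(a$v^2)) / d[3])
}

check_atlas_dims <- function(atlas_dims) {
  if (!is.numeric(atlas_dims) || length(atlas_dims) != 3L ||
      any(atlas_dims < 1)) {
    stop("atlas_dims must be a positive 3-vector (Nx, Ny, Nz)", call. = FALSE)
  }
  as.numeric(atlas_dims)
}

#' Default axis-aligned anchoring plane
#'
#' The standard full-extent plane perpendicular to one principal axis, at a
#' given voxel position along that axis. Used for the initial even
#' distribution of an unanchored series.
#'
#' @param axis One of `"coronal"` (y), `"sagittal"` (x), `"horizontal"` (z).
#' @param position Voxel coordinate along the chosen axis.
#' @inheritParams pose_to_anchoring
#' @return An [anchoring()].
#' @export
default_plane <- function(axis = c("coronal", "sagittal", "horizontal"),
                          position, atlas_dims) {
  axis <- match.arg(axis)
  d <- check_atlas_dims(atlas_dims)
  switch(axis,
    coronal    = anchoring(o = c(0, position, d[3]),
                           u = c(d[1], 0, 0), v = c(0, 0, -d[3])),
    sagittal   = anchoring(o = c(position, 0, d[3]),
                           u = c(0, d[2], 0), v = c(0, 0, -d[3])),
    horizontal = anchoring(o = c(0, d[2], position),
                           u = c(d[1], 0, 0), v = c(0, -d[2], 0))
  )
}
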