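#' Reference atlas spaces and voxel-to-physical transforms
#'
#' Two published reference spaces ship built in, each defined by a 4x4
#' affine in row-vector convention, `(x y z 1) %*% M`, exactly as published:
#'
#' * `"allen_ccfv3"` — Allen Mouse Brain CCF v3. Physical output in
#'   micrometers, PIR axis order (posterior, inferior, right):
#'   `x_a = 13175 - 25 y_v`, `y_a = 7975 - 25 z_v`, `z_a = 25 x_v`.
#' * `"whs_rat"` — Waxholm Space rat atlas. Physical output in millimeters,
#'   RAS axis order, isotropic 0.0390625 mm voxels with origin offset
#'   `(-9.53125, -24.3359375, -9.6875)`.
#'
#' The matrices are stored as published rather than re-derived from
#' resolution constants; the Allen matrix in particular encodes an axis
#' reordering (voxel RAS to physical PIR) that a scale-plus-offset
#' derivation would miss.
#'
#' @param name Space name: `"allen_ccfv3"`, `"whs_rat"`, an abbreviation
#'   (`"allen"`, `"whs"`), or a name registered via [register_atlas_space()].
#' @return An object of class `atlas_space` with fields `name`,
#'   `axis_order_out`, `units_out` and `matrix`.
#' @export
atlas_space <- function(name) {
  if (inherits(name, "atlas_space")) return(name)
  key <- switch(tolower(name),
                allen = , allen_ccfv3 = "allen_ccfv3",
                whs = , whs_rat = "whs_rat",
                tolower(name))
  sp <- .space_registry[[key]]
  if (is.null(sp)) {
    stop("unknown atlas space '", name,
         "' (built-in: allen_ccfv3, whs_rat; see register_atlas_space())",
         call. = FALSE)
  }
  sp
}

.space_registry <- new.env(parent = emptyenv())

new_atlas_space <- function(name, matrix, axis_order_out, units_out) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(4, 4)))
  if (!isTRUE(all.equal(matrix[, 4], c(0, 0, 0, 1)))) {
    stop("space matrix last column must be (0,0,0,1) in row-vector convention",
         call. = FALSE)
  }
  if (abs(det(matrix)) < .Machine$double.eps) {
    stop("space matrix must be invertible", call. = FALSE)
  }
  structure(list(name = name, axis_order_out = axis_order_out,
                 units_out = units_out, matrix = matrix),
            class = "atlas_space")
}

#' Register a custom atlas space
#'
#' @inheritParams atlas_space
#' @param matrix 4x4 affine, row-vector convention: physical = (voxel, 1)
#'   times `matrix`; last column `(0, 0, 0, 1)`.
#' @param axis_order_out Three-letter label for the physical axis order
#'   (e.g. `"RAS"`).
#' @param units_out Unit label for physical coordinates (e.g. `"mm"`).
#' @return The registered `atlas_space`, invisibly.
#' @export
register_atlas_space <- function(name, matrix, axis_order_out = "RAS",
                                 units_out = "mm") {
  sp <- new_atlas_space(tolower(name), matrix, axis_order_out, units_out)
  assign(tolower(name), sp, envir = .space_registry)
  invisible(sp)
}

# built-in matrices, stored exactly as published (row-vector convention)
local({
  allen <- matrix(c(
        0,     0,  25, 0,
      -25,     0,   0, 0,
        0,   -25,   0, 0,
    13175,  7975,   0, 1), nrow = 4, byrow = TRUE)
  whs <- matrix(c(
    0.0390625, 0, 0, 0,
    0, 0.0390625, 0, 0,
    0, 0, 0.0390625, 0,
    -9.53125, -24.3359375, -9.6875, 1), nrow = 4, byrow = TRUE)
  assign("allen_ccfv3",
         new_atlas_space("allen_ccfv3", allen, "PIR", "um"),
         envir = .space_registry)
  assign("whs_rat",
         new_atlas_space("whs_rat", whs, "RAS", "mm"),
         envir = .space_registry)
})

#' @export
print.atlas_space <- function(x, ...) {
  cat(sprintf("<atlas_space> %s: physical coords in %s, %s axis order\n",
              x$name, x$units_out, x$axis_order_out))
  print(x$matrix)
  invisible(x)
}

label_physical <- function(space, p) {
  if (is.matrix(p)) {
    colnames(p) <- strsplit(space$axis_order_out, "")[[1]]
  } else {
    names(p) <- strsplit(space$axis_order_out, "")[[1]]
  }
  p
}

#' Convert atlas voxel coordinates to physical space
#'
#' @param space An [atlas_space()] or space name.
#' @param v Numeric 3-vector in atlas voxels, or an `n x 3` matrix of
#'   points.
#' @return Physical coordinates (in the space's units), labelled with the
#'   space's output axis order so PIR/RAS confusion is visible in the
#'   result.
#' @export
voxel_to_physical <- function(space, v) {
  space <- atlas_space(space)
  pts <- if (is.matrix(v)) v else matrix(as.numeric(v), nrow = 1)
  stopifnot(ncol(pts) == 3)
  out <- cbind(pts, 1) %*% space$matrix
  out <- out[, 1:3, drop = !is.matrix(v)]
  label_physical(space, out)
}

#' Convert physical coordinates back to atlas voxels
#'
#' Exact affine inverse of [voxel_to_physical()].
#'
#' @inheritParams voxel_to_physical
#' @param p Physical coordinates: 3-vector or `n x 3` matrix, in the
#'   space's units and axis order.
#' @return Atlas voxel coordinates (unlabelled RAS voxel order).
#' @export
physical_to_voxel <- function(space, p) {
  space <- atlas_space(space)
  pts <- if (is.matrix(p)) p else matrix(as.numeric(p), nrow = 1)
  stopifnot(ncol(pts) == 3)
  out <- cbind(pts, 1) %*% solve(space$matrix)
  out <- out[, 1:3, drop = !is.matrix(p)]
  if (is.matrix(out)) colnames(out) <- c("x", "y", "z") else names(out) <- c("x", "y", "z")
  out
}

#' Map an image pixel directly to physical atlas coordinates
#'
#' Composition of [pixel_to_voxel()] and [voxel_to_physical()]: the readout
#' used to collect, e.g., electrode-tract positions from anchored sections.
#'
#' @inheritParams voxel_to_physical
#' @inheritParams pixel_to_voxel
#' @return Labelled physical coordinates.
#' @export
pixel_to_physical <- function(space, a, x, y, width, height) {
  voxel_to_physical(space, pixel_to_voxel(a, x, y, width, height))
}
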