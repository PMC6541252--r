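#' Anchoring vectors: placing a 2D section plane in atlas voxel space
#'
#' A section image is placed in the reference atlas by three vectors in
#' atlas voxel coordinates: `o` points from the atlas origin to the top-left
#' corner of the corresponding atlas slice, `u` from `o` to its top-right
#' corner (the horizontal image edge) and `v` from `o` to its bottom-left
#' corner (the vertical image edge). Any pixel `(x, y)` of a `w`-by-`h` image
#' then maps to the continuous voxel coordinate `o + (x/w) u + (y/h) v`.
#'
#' The atlas voxel frame follows the RAS convention: the origin is the
#' bottom-left corner of the most anterior coronal plane, x grows left to
#' right, y posterior to anterior, z inferior to superior.
#'
#' @param o,u,v Numeric 3-vectors in atlas voxels.
#' @return An object of class `anchoring`, a list with elements `o`, `u`, `v`.
#' @examples
#' a <- anchoring(o = c(312.2, 533.8, 218.4),
#'                u = c(-185.7, -35.5, 6.6),
#'                v = c(-4.6, -7.5, -171.4))
#' pixel_to_voxel(a, 0, 0, width = 24723, height = 18561)
#' @export
anchoring <- function(o, u, v) {
  if (!is_number3(o) || !is_number3(u) || !is_number3(v)) {
    stop("anchoring vectors o, u, v must each be finite numeric 3-vectors",
         call. = FALSE)
  }
  structure(list(o = as.numeric(o), u = as.numeric(u), v = as.numeric(v)),
            class = "anchoring")
}

#' @export
print.anchoring <- function(x, ...) {
  cat("<anchoring>\n")
  cat("  o:", paste(fmt_double(x$o), collapse = ", "), "\n")
  cat("  u:", paste(fmt_double(x$u), collapse = ", "), "\n")
  cat("  v:", paste(fmt_double(x$v), collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.anchoring <- function(x, ...) {
  paste0("anchoring(o=[", paste(fmt_double(x$o), collapse = ","),
         "], u=[", paste(fmt_double(x$u), collapse = ","),
         "], v=[", paste(fmt_double(x$v), collapse = ","), "])")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Plane unit normal of an anchoring
#'
#' The normal is `(u x v) / |u x v|`; its sign convention fixes the sign of
#' the out-of-plane distance reported by [voxel_to_pixel()].
#'
#' @param a An [anchoring()].
#' @return Unit numeric 3-vector.
#' @export
anchoring_normal <- function(a) {
  n <- cross3(a$u, a$v)
  nn <- sqrt(sum(n^2))
  if (nn == 0) {
    stop("degenerate anchoring: u and v are collinear, plane normal undefined",
         call. = FALSE)
  }
  n / nn
}

#' Map image pixels to continuous atlas voxel coordinates
#'
#' Implements the weighted-sum mapping `o + (x/w) u + (y/h) v`. Pixel
#' coordinates may be fractional and may lie outside `[0, w] x [0, h]`
#' (extrapolation beyond the image is permitted). Weights are `x/w`, not
#' `x/(w-1)`: the top-left pixel (0,0) maps exactly to `o` and the point
#' `(w, h)` maps exactly to `o + u + v`.
#'
#' @param a An [anchoring()].
#' @param x,y Pixel coordinates (vectors of equal length are accepted).
#' @param width,height Image dimensions in pixels (the dimensions the
#'   anchoring refers to, typically the original full-resolution image).
#' @return For scalar input a numeric 3-vector `(x_v, y_v, z_v)`; for vector
#'   input an `n x 3` matrix with one row per pixel.
#' @seealso [voxel_to_pixel()] for the inverse, [anchoring_matrix()] for the
#'   matrix form.
#' @export
pixel_to_voxel <- function(a, x, y, width, height) {
  stopifnot(inherits(a, "anchoring"))
  check_dims(width, height)
  s <- x / width
  t <- y / height
  out <- cbind(a$o[1] + s * a$u[1] + t * a$v[1],
               a$o[2] + s * a$u[2] + t * a$v[2],
               a$o[3] + s * a$u[3] + t * a$v[3])
  colnames(out) <- c("x", "y", "z")
  if (length(x) == 1L && length(y) == 1L) drop(out) else out
}

check_dims <- function(width, height) {
  if (!is.numeric(width) || !is.numeric(height) ||
      any(width < 1) || any(height < 1)) {
    stop("image dimensions must be >= 1 pixel", call. = FALSE)
  }
  invisible(TRUE)
}

#' Map an atlas voxel coordinate back to image pixels
#'
#' Decomposes `p - o = s u + t v + d n` with `n = (u x v)/|u x v|` and
#' returns `(x = s w, y = t h, d)`, where `d` is the signed out-of-plane
#' distance in voxels. In-plane points round-trip [pixel_to_voxel()].
#'
#' @param a A non-degenerate [anchoring()] (`|u x v| > 0`).
#' @param p Numeric 3-vector, continuous atlas voxel coordinate.
#' @inheritParams pixel_to_voxel
#' @return Named numeric vector `c(x, y, d)`.
#' @export
voxel_to_pixel <- function(a, p, width, height) {
  stopifnot(inherits(a, "anchoring"), is_number3(p))
  check_dims(width, height)
  n <- anchoring_normal(a)
  basis <- cbind(a$u, a$v, n)
  std <- unname(solve(basis, as.numeric(p) - a$o))
  c(x = std[1] * width, y = std[2] * height, d = std[3])
}

#' Pixel-to-voxel mapping as a 3x3 matrix
#'
#' Returns `M` with rows `u`, `v`, `o` such that
#' `(x_v, y_v, z_v) = (x/w, y/h, 1) %*% M`, equivalent to
#' [pixel_to_voxel()].
#'
#' @inheritParams pixel_to_voxel
#' @return A 3x3 numeric matrix.
#' @export
anchoring_matrix <- function(a) {
  stopifnot(inherits(a, "anchoring"))
  m <- rbind(a$u, a$v, a$o)
  dimnames(m) <- list(c("u", "v", "o"), c("x", "y", "z"))
  m
}
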