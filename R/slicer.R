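#' Custom atlas slices
#'
#' A custom atlas slice (atlas plate) is the 2D image obtained by
#' resampling an atlas volume along a section's anchoring plane, generated
#' at the native resolution of the atlas (1 plate pixel per atlas voxel
#' along each edge). Plates are typically much smaller than the original
#' section images; the viewer stretches the plate over the image so that
#' all four plate corners land on the image corners.
#'
#' @name custom_slice
NULL

new_custom_slice <- function(pixels, source_volume, anchoring, kind) {
  structure(list(pixels = pixels,
                 c_w = ncol(pixels), c_h = nrow(pixels),
                 source_volume = source_volume,
                 anchoring = anchoring, kind = kind),
            class = "custom_slice")
}

#' @export
print.custom_slice <- function(x, ...) {
  cat(sprintf("<custom_slice> %d x %d px from '%s' (%s)\n",
              x$c_w, x$c_h, x$source_volume, x$kind))
  invisible(x)
}

#' Native plate dimensions of an anchoring
#'
#' At native atlas resolution one plate pixel corresponds to one voxel
#' along each plane edge: `c_w = max(1, round(|u|))`,
#' `c_h = max(1, round(|v|))`.
#'
#' @param a A non-degenerate [anchoring()].
#' @return Integer vector `c(c_w, c_h)`.
#' @export
native_slice_dims <- function(a) {
  stopifnot(inherits(a, "anchoring"))
  nu <- sqrt(sum(a$u^2)); nv <- sqrt(sum(a$v^2))
  if (nu == 0 || nv == 0) {
    stop("anchoring has a zero-length edge vector; no plate dimensions",
         call. = FALSE)
  }
  c(c_w = max(1L, as.integer(round(nu))), c_h = max(1L, as.integer(round(nv))))
}

#' Resample an atlas volume along an anchoring plane
#'
#' Plate pixel `(i, j)` (column `i = 0..c_w-1`, row `j = 0..c_h-1`)
#' samples the volume at `o + (i/c_w) u + (j/c_h) v`, with the same `x/w`
#' weight convention as the pixel-to-voxel mapping. Segmentation volumes
#' are always sampled nearest-neighbour; points outside the volume yield
#' background 0.
#'
#' @param vol An [atlas_volume()].
#' @param a An [anchoring()].
#' @param c_w,c_h Plate dimensions in pixels; default
#'   [native_slice_dims()].
#' @inheritParams sample_volume
#' @return A `custom_slice` whose `pixels` matrix has `c_h` rows (top
#'   image row first) and `c_w` columns.
#' @export
render_slice <- function(vol, a, c_w = NULL, c_h = NULL,
                         method = c("nearest", "trilinear")) {
  stopifnot(inherits(vol, "atlas_volume"), inherits(a, "anchoring"))
  method <- match.arg(method)
  if (vol$kind == "segmentation") method <- "nearest"
  if (is.null(c_w) || is.null(c_h)) {
    nd <- native_slice_dims(a)
    c_w <- c_w %||% nd[["c_w"]]
    c_h <- c_h %||% nd[["c_h"]]
  }
  stopifnot(c_w >= 1, c_h >= 1)
  s <- rep((0:(c_w - 1)) / c_w, times = c_h)
  t <- rep((0:(c_h - 1)) / c_h, each = c_w)
  pts <- cbind(a$o[1] + s * a$u[1] + t * a$v[1],
               a$o[2] + s * a$u[2] + t * a$v[2],
               a$o[3] + s * a$u[3] + t * a$v[3])
  vals <- sample_volume(vol, pts, method = method)
  pixels <- matrix(vals, nrow = c_h, ncol = c_w, byrow = TRUE)
  if (vol$kind == "segmentation") storage.mode(pixels) <- "integer"
  new_custom_slice(pixels, vol$name, a, vol$kind)
}

#' Map original-image pixel coordinates onto the matching plate
#'
#' Scaling along the horizontal and vertical axes is done separately:
#' `c_x = x * c_w / w`, `c_y = y * c_h / h`, for `x = 0..(w-1)`,
#' `y = 0..(h-1)`; the resulting continuous plate coordinates satisfy
#' `0 <= c_x < c_w`, `0 <= c_y < c_h`.
#'
#' @param x,y Pixel coordinates in the original image (vectorized).
#' @param width,height Original image dimensions in pixels.
#' @param c_w,c_h Plate dimensions in pixels.
#' @return For scalar input a named vector `c(c_x, c_y)`, else an
#'   `n x 2` matrix.
#' @export
image_to_slice_coords <- function(x, y, width, height, c_w, c_h) {
  check_dims(width, height)
  out <- cbind(c_x = x * c_w / width, c_y = y * c_h / height)
  if (length(x) == 1L && length(y) == 1L) drop(out) else out
}

# ---- .flat binary raster ----------------------------------------------------

#' Read and write .flat label rasters
#'
#' The `.flat` format is an uncompressed big-endian raster of atlas region
#' identifiers: offset 0, one byte `Bpp` (bytes per pixel, 1 or 2);
#' offset 1, 32-bit width in pixels; offset 5, 32-bit height; offset 9,
#' `Bpp * width * height` bytes of pixel data. Pixels are stored row-major
#' with the top image row first, matching PNG raster order so that the
#' `.flat` and the segmentation PNG of the same plate align
#' index-for-index. `Bpp` is 1 when the largest label fits a byte, else 2;
#' labels above 65535 are an error.
#'
#' @param x For `write_flat()`: a `custom_slice` (segmentation kind) or an
#'   integer matrix (rows = image rows); for `read_flat()`: a raw vector
#'   or path to a `.flat` file.
#' @return `write_flat()`: a raw vector (or `path` invisibly);
#'   `read_flat()`: an integer matrix.
#' @param path Optional output file for `write_flat()`.
#' @export
write_flat <- function(x, path = NULL) {
  grid <- if (inherits(x, "custom_slice")) x$pixels else x
  stopifnot(is.matrix(grid))
  vals <- as.integer(t(grid))  # row-major, top row first
  if (anyNA(vals) || any(vals < 0)) {
    stop("flat rasters hold non-negative integer labels", call. = FALSE)
  }
  mx <- if (length(vals)) max(vals) else 0L
  if (mx > 65535L) stop("label ", mx, " does not fit in 2 bytes", call. = FALSE)
  bpp <- if (mx <= 255L) 1L else 2L
  dim_bytes <- function(n) as.raw(c(n %/% 16777216L, (n %/% 65536L) %% 256L,
                                    (n %/% 256L) %% 256L, n %% 256L))
  payload <- if (bpp == 1L) {
    as.raw(vals)
  } else {
    as.raw(as.vector(rbind(vals %/% 256L, vals %% 256L)))
  }
  out <- c(as.raw(bpp), dim_bytes(ncol(grid)), dim_bytes(nrow(grid)), payload)
  if (!is.null(path)) {
    writeBin(out, path)
    return(invisible(path))
  }
  out
}

#' @rdname write_flat
#' @export
read_flat <- function(x) {
  r <- if (is.raw(x)) x else readBin(x, "raw", n = file.size(x))
  if (length(r) < 9) stop("truncated .flat buffer: no header", call. = FALSE)
  bpp <- as.integer(r[1])
  if (!bpp %in% c(1L, 2L)) {
    stop(".flat format error: Bpp must be 1 or 2, got ", bpp, call. = FALSE)
  }
  be32 <- function(b) sum(as.integer(b) * c(16777216, 65536, 256, 1))
  w <- be32(r[2:5]); h <- be32(r[6:9])
  need <- 9 + bpp * w * h
  if (length(r) != need) {
    stop("truncated .flat buffer: expected ", need, " bytes, got ",
         length(r), call. = FALSE)
  }
  body <- as.integer(r[-(1:9)])
  vals <- if (bpp == 1L) body else {
    body[c(TRUE, FALSE)] * 256L + body[c(FALSE, TRUE)]
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

# ---- region lookup ----------------------------------------------------------

#' Look up the atlas region under an image pixel
#'
#' Maps the pixel through the anchoring to continuous voxel coordinates,
#' takes the nearest-voxel segmentation label and attaches its palette
#' name. Pixels mapping outside the volume report the background label 0.
#'
#' @param seg A segmentation [atlas_volume()].
#' @param palette An [atlas_palette()].
#' @inheritParams pixel_to_voxel
#' @return A tibble with columns `x`, `y`, `id`, `name` (one row per
#'   pixel). Labels missing from the palette keep their `id` with `name`
#'   `NA` and a warning.
#' @export
lookup_region <- function(seg, palette, a, x, y, width, height) {
  stopifnot(inherits(seg, "atlas_volume"), seg$kind == "segmentation",
            inherits(palette, "atlas_palette"))
  v <- pixel_to_voxel(a, x, y, width, height)
  if (!is.matrix(v)) v <- matrix(v, nrow = 1)
  id <- as.integer(sample_volume(seg, v, "nearest"))
  name <- palette$name[match(id, palette$index)]
  if (anyNA(name)) {
    warning("label(s) missing from palette: ",
            paste(unique(id[is.na(name)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(x = x, y = y, id = id, name = name)
}

# ---- series export ----------------------------------------------------------

#' Export atlas plates for every anchored section of a series
#'
#' For each section with an anchoring (estimated or verified) and each
#' volume, resamples the volume along the section plane at native atlas
#' resolution and writes the artifacts into a timestamped subfolder
#' `Slices-YYYYMMDDHHmmSS` under `out_root`:
#'
#' * per template volume, a 24-bit truecolor PNG
#'   `"<original filename>-<template name>.png"` (grayscale intensities
#'   replicated across channels, scaled by the volume's global range);
#' * per segmentation volume, both a palette-coloured PNG
#'   `"<original filename>-<segmentation name>.png"` and a
#'   `"<original filename>-<segmentation name>.flat"` label raster;
#' * one `"<segmentation name>.json"` palette file per segmentation.
#'
#' Sections without an anchoring are skipped with a warning. If the target
#' folder already exists a numeric suffix is appended.
#'
#' @param s A [section_series()].
#' @param volumes A list of [atlas_volume()] objects (any mix of templates
#'   and segmentations).
#' @param palette An [atlas_palette()]; required when `volumes` contains a
#'   segmentation.
#' @param out_root Directory in which to create the timestamped folder.
#' @param method Sampling method for templates (segmentations are always
#'   nearest).
#' @param timestamp Folder timestamp string; defaults to the current local
#'   time, injectable for reproducible output.
#' @return Character vector of written file paths (invisibly the folder is
#'   first).
#' @export
export_series <- function(s, volumes, palette = NULL, out_root = ".",
                          method = c("nearest", "trilinear"),
                          timestamp = format(Sys.time(), "%Y%m%d%H%M%S")) {
  stopifnot(inherits(s, "section_series"))
  method <- match.arg(method)
  if (inherits(volumes, "atlas_volume")) volumes <- list(volumes)
  has_seg <- any(vapply(volumes, function(v) v$kind == "segmentation", logical(1)))
  if (has_seg && is.null(palette)) {
    stop("a palette is required to export segmentation volumes", call. = FALSE)
  }
  folder <- file.path(out_root, paste0("Slices-", timestamp))
  suffix <- 0
  while (dir.exists(folder)) {
    suffix <- suffix + 1
    folder <- file.path(out_root, paste0("Slices-", timestamp, "-", suffix))
  }
  dir.create(folder, recursive = TRUE)
  written <- character()

  for (vol in volumes) {
    if (vol$kind == "segmentation") {
      pal_path <- file.path(folder, paste0(vol$name, ".json"))
      write_palette(palette, pal_path)
      written <- c(written, pal_path)
    }
  }

  tmpl_range <- lapply(volumes, function(v) {
    if (v$kind == "template") range(v$data) else NULL
  })

  for (i in seq_len(nrow(s))) {
    a <- slice_anchoring(s, s$nr[i])
    if (is.null(a)) {
      warning("section nr ", s$nr[i], " (", s$filename[i],
              ") has no anchoring; skipped", call. = FALSE)
      next
    }
    nd <- native_slice_dims(a)
    for (k in seq_along(volumes)) {
      vol <- volumes[[k]]
      sl <- render_slice(vol, a, nd[["c_w"]], nd[["c_h"]], method = method)
      stem <- file.path(folder, paste0(s$filename[i], "-", vol$name))
      if (vol$kind == "template") {
        png_path <- paste0(stem, ".png")
        png::writePNG(slice_to_rgb(sl, range = tmpl_range[[k]]), png_path)
        written <- c(written, png_path)
      } else {
        png_path <- paste0(stem, ".png")
        png::writePNG(slice_to_rgb(sl, palette = palette), png_path)
        flat_path <- paste0(stem, ".flat")
        write_flat(sl, flat_path)
        written <- c(written, png_path, flat_path)
      }
      message("exported ", basename(stem), " (", sl$c_w, "x", sl$c_h, ")")
    }
  }
  attr(written, "folder") <- folder
  written
}

# 24-bit truecolor pixel array for a plate: palette colours for
# segmentations, range-scaled grayscale replicated across channels for
# templates
slice_to_rgb <- function(sl, palette = NULL, range = NULL) {
  px <- sl$pixels
  if (sl$kind == "segmentation") {
    pos <- match(px, palette$index)
    if (anyNA(pos)) {
      stop("plate contains label(s) missing from the palette: ",
           paste(unique(px[is.na(pos)]), collapse = ", "), call. = FALSE)
    }
    arr <- array(0, dim = c(nrow(px), ncol(px), 3))
    arr[, , 1] <- palette$red[pos] / 255
    arr[, , 2] <- palette$green[pos] / 255
    arr[, , 3] <- palette$blue[pos] / 255
  } else {
    range <- range %||% range(px)
    span <- diff(range)
    g <- if (span == 0) array(0, dim = dim(px)) else (px - range[1]) / span
    arr <- array(rep(g, 3), dim = c(nrow(px), ncol(px), 3))
  }
  arr
}

#' Plot a custom slice
#'
#' @param object A `custom_slice`.
#' @param palette Optional [atlas_palette()] for segmentation plates.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.custom_slice <- function(object, palette = NULL, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for autoplot()", call. = FALSE)
  }
  px <- object$pixels
  df <- tibble::tibble(
    c_x = rep(seq_len(ncol(px)) - 1L, each = nrow(px)),
    c_y = rep(seq_len(nrow(px)) - 1L, times = ncol(px)),
    value = as.vector(px))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$c_x, .data$c_y)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$source_volume, x = "c_x", y = "c_y")
  if (object$kind == "segmentation" && !is.null(palette)) {
    cols <- grDevices::rgb(palette$red, palette$green, palette$blue,
                           maxColorValue = 255)
    names(cols) <- as.character(palette$index)
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::scale_fill_manual(values = cols, name = "label")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   name = "intensity")
  }
}
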