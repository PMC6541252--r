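#' Atlas volumes
#'
#' A reference atlas volume is a 3D grid indexed `(x, y, z)` in the RAS
#' voxel convention: origin at the bottom-left corner of the most anterior
#' coronal plane, x growing left to right, y posterior to anterior, z
#' inferior to superior. Voxel coordinates are plain 0-based indices into
#' the grid. Two kinds exist: `"template"` (finite scalar intensities, e.g.
#' MRI or Nissl) and `"segmentation"` (non-negative integer region labels,
#' 0 = background).
#'
#' @param data 3D numeric array, indexed `[x+1, y+1, z+1]` for voxel
#'   `(x, y, z)`.
#' @param kind `"template"` or `"segmentation"`.
#' @param space Name of the associated [atlas_space()], or `NA`.
#' @param name Volume name used in export filenames (e.g. `"MRI"`,
#'   `"segmentation"`).
#' @return An object of class `atlas_volume`.
#' @export
atlas_volume <- function(data, kind = c("template", "segmentation"),
                         space = NA_character_, name = kind[1]) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("atlas volume data must be a 3D array", call. = FALSE)
  }
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (kind == "segmentation") {
    if (anyNA(data) || any(data < 0) || any(data != floor(data))) {
      stop("segmentation volumes must contain non-negative integer labels",
           call. = FALSE)
    }
    storage.mode(data) <- "integer"
  } else {
    if (!all(is.finite(data))) {
      stop("template volumes must contain finite values", call. = FALSE)
    }
    storage.mode(data) <- "double"
  }
  structure(list(data = data, kind = kind, dims = dim(data),
                 space = space, name = name),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat(sprintf("<atlas_volume> '%s' (%s): %d x %d x %d voxels\n",
              x$name, x$kind, x$dims[1], x$dims[2], x$dims[3]))
  invisible(x)
}

#' Load an atlas volume from a NIfTI file
#'
#' The grid is reindexed so that its axes follow the RAS voxel convention,
#' using the file's affine only to detect axis order and flips. Only
#' axis-permutation/flip affines are honoured: an oblique affine is an
#' error, since the voxel frame is axis-aligned by definition. After
#' loading, voxel coordinates are plain indices; the affine plays no
#' further role (physical coordinates come from [voxel_to_physical()]).
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D volume.
#' @inheritParams atlas_volume
#' @return An [atlas_volume()].
#' @export
load_volume <- function(path, kind = c("template", "segmentation"),
                        space = NA_character_, name = NULL) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path,
         call. = FALSE)
  }
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0) {
    check_axis_aligned(RNifti::xform(img), path)
    RNifti::orientation(img) <- "RAS"
  }  # no spatial transform recorded: grid is taken to be RAS already
  arr <- as.array(img)
  atlas_volume(arr, kind = kind, space = space,
               name = name %||% sub("\\.nii(\\.gz)?$", "", basename(path)))
}

check_axis_aligned <- function(xf, path) {
  r <- xf[1:3, 1:3]
  nz <- abs(r) > 1e-6 * max(abs(r))
  if (any(rowSums(nz) != 1) || any(colSums(nz) != 1)) {
    stop("oblique affine in '", path,
         "': only axis-permutation/flip orientations are supported",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write an atlas volume to a NIfTI file
#'
#' Written with an identity-scaled RAS affine, so that
#' `load_volume(write_volume(v))` reproduces the grid exactly.
#'
#' @param vol An [atlas_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "atlas_volume"))
  img <- RNifti::asNifti(vol$data)
  aff <- diag(4)
  aff[1:3, 4] <- -(vol$dims - 1) / 2  # centred, unit-voxel RAS affine
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Sample an atlas volume at continuous voxel coordinates
#'
#' Nearest-neighbour rounds half up on each axis (`floor(c + 0.5)`);
#' trilinear performs standard 8-neighbour interpolation and is only
#' allowed for templates — region labels must never be blended. Any sample
#' point outside `[0, N-1]` on any axis yields the background value 0.
#'
#' @param vol An [atlas_volume()].
#' @param p Continuous voxel coordinates: numeric 3-vector or `n x 3`
#'   matrix.
#' @param method `"nearest"` (default, exact lookup on integer
#'   coordinates) or `"trilinear"`.
#' @return Numeric vector of sampled values (scalar for 3-vector input).
#' @export
sample_volume <- function(vol, p, method = c("nearest", "trilinear")) {
  stopifnot(inherits(vol, "atlas_volume"))
  method <- match.arg(method)
  if (method == "trilinear" && vol$kind == "segmentation") {
    stop("trilinear sampling is not allowed on segmentation volumes: ",
         "labels must never be blended", call. = FALSE)
  }
  pts <- if (is.matrix(p)) p else matrix(as.numeric(p), nrow = 1)
  stopifnot(ncol(pts) == 3)
  d <- vol$dims
  inb <- pts[, 1] >= 0 & pts[, 1] <= d[1] - 1 &
         pts[, 2] >= 0 & pts[, 2] <= d[2] - 1 &
         pts[, 3] >= 0 & pts[, 3] <= d[3] - 1
  out <- numeric(nrow(pts))
  if (any(inb)) {
    q <- pts[inb, , drop = FALSE]
    if (method == "nearest") {
      # half-up rounding cannot leave [0, N-1] when q itself is inside
      idx <- round_half_up(q)
      out[inb] <- vol$data[1 + idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3])]
    } else {
      i0 <- floor(q)
      f <- q - i0
      acc <- numeric(nrow(q))
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        wx <- if (dx == 0) 1 - f[, 1] else f[, 1]
        wy <- if (dy == 0) 1 - f[, 2] else f[, 2]
        wz <- if (dz == 0) 1 - f[, 3] else f[, 3]
        ix <- i0[, 1] + dx; iy <- i0[, 2] + dy; iz <- i0[, 3] + dz
        ok <- ix <= d[1] - 1 & iy <= d[2] - 1 & iz <= d[3] - 1
        val <- numeric(nrow(q))
        val[ok] <- vol$data[1 + ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok])]
        acc <- acc + wx * wy * wz * val
      }
      out[inb] <- acc
    }
  }
  if (!is.matrix(p)) out[1] else out
}

# ---- palettes ---------------------------------------------------------------

#' Segmentation palettes
#'
#' A palette assigns each segmentation label a colour and a region name: an
#' ordered list of `(index, red, green, blue, name)` tuples where entry `k`
#' has `index == k` (the index is deliberately redundant — it mirrors the
#' array position, and the invariant is enforced).
#'
#' @param index Integer vector `0, 1, 2, ...` (must equal positions - 1).
#' @param red,green,blue Integer vectors in 0-255.
#' @param name Character vector of region names.
#' @return A tibble of class `atlas_palette`.
#' @export
atlas_palette <- function(index, red, green, blue, name) {
  p <- tibble::tibble(index = as.integer(index), red = as.integer(red),
                      green = as.integer(green), blue = as.integer(blue),
                      name = as.character(name))
  if (!identical(p$index, seq_len(nrow(p)) - 1L)) {
    stop("palette index must equal the array position (entry k has index k)",
         call. = FALSE)
  }
  rng <- range(c(p$red, p$green, p$blue))
  if (rng[1] < 0 || rng[2] > 255) {
    stop("palette colour components must be in 0-255", call. = FALSE)
  }
  structure(p, class = c("atlas_palette", class(tibble::tibble())))
}

#' Write or read a palette as JSON
#'
#' The on-disk form is a JSON array of `[index, red, green, blue, name]`
#' tuples — four numbers then a string.
#'
#' @param p An [atlas_palette()].
#' @param path Optional output file; when `NULL` the JSON text is returned.
#' @return `write_palette()`: the JSON text or `path` (invisibly);
#'   `read_palette()`: an [atlas_palette()].
#' @export
write_palette <- function(p, path = NULL) {
  stopifnot(inherits(p, "atlas_palette"))
  tuples <- lapply(seq_len(nrow(p)), function(i) {
    list(p$index[i], p$red[i], p$green[i], p$blue[i], p$name[i])
  })
  txt <- as.character(jsonlite::toJSON(tuples, auto_unbox = TRUE))
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(path))
  }
  txt
}

#' @rdname write_palette
#' @param x Path to a palette JSON file, or literal JSON text.
#' @export
read_palette <- function(x) {
  tuples <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  atlas_palette(index = vapply(tuples, function(t) as.integer(t[[1]]), integer(1)),
                red   = vapply(tuples, function(t) as.integer(t[[2]]), integer(1)),
                green = vapply(tuples, function(t) as.integer(t[[3]]), integer(1)),
                blue  = vapply(tuples, function(t) as.integer(t[[4]]), integer(1)),
                name  = vapply(tuples, function(t) as.character(t[[5]]), character(1)))
}

# ---- synthetic atlas --------------------------------------------------------

#' Generate a synthetic reference atlas for testing
#'
#' Stands in for the (large, downloadable) published atlas volumes in tests
#' and examples; it is synthetic and emulates only the structural features
#' the registration machinery relies on. The segmentation consists of
#' `n_regions` nested axis-aligned boxes, labels `1..n_regions` from
#' outermost to innermost on background 0, so every region's voxel count
#' has a closed form and the grid centre always carries the innermost
#' label. The template is a smooth separable gradient plus a
#' region-dependent intensity offset, so template and segmentation share
#' anatomy-like structure. Output is deterministic in `seed` (used for the
#' palette colours and gradient amplitudes).
#'
#' Box `k` (1-based) spans, on each axis of extent `N`,
#' `floor(N * k / (2 * (n_regions + 1))) <= i < N - floor(...)`.
#'
#' @param dims Integer 3-vector `(Nx, Ny, Nz)`, each at least 8.
#' @param n_regions Number of nested regions, at least 1.
#' @param seed Integer seed.
#' @return A list with elements `template`, `segmentation` (both
#'   [atlas_volume()]) and `palette` ([atlas_palette()], `n_regions + 1`
#'   entries with distinct colours).
#' @export
make_synthetic_atlas <- function(dims = c(64, 80, 56), n_regions = 3,
                                 seed = 1) {
  dims <- as.integer(check_atlas_dims(dims))
  if (any(dims < 8)) stop("synthetic atlas dims must each be >= 8", call. = FALSE)
  if (n_regions < 1) stop("n_regions must be >= 1", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  seg <- array(0L, dim = dims)
  for (k in seq_len(n_regions)) {
    lo <- floor(dims * k / (2 * (n_regions + 1)))       # 0-based inclusive
    hi <- dims - lo                                     # 0-based exclusive
    seg[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]] <- k
  }

  amp <- stats::runif(3, 10, 30)
  gx <- amp[1] * seq(0, 1, length.out = dims[1])
  gy <- amp[2] * seq(0, 1, length.out = dims[2])
  gz <- amp[3] * seq(0, 1, length.out = dims[3])
  tmpl <- outer(outer(gx, gy, `+`), gz, `+`) + 10 * seg

  cols <- distinct_colors(n_regions)
  pal <- atlas_palette(index = 0:n_regions,
                       red = c(0L, cols[, 1]),
                       green = c(0L, cols[, 2]),
                       blue = c(0L, cols[, 3]),
                       name = c("background",
                                paste0("region_", seq_len(n_regions))))
  list(template = atlas_volume(tmpl, "template", name = "template"),
       segmentation = atlas_volume(seg, "segmentation", name = "segmentation"),
       palette = pal)
}

# sample distinct non-black colours from a 6x6x6 colour cube
distinct_colors <- function(n) {
  grid <- as.matrix(expand.grid(r = seq(0L, 255L, by = 51L),
                                g = seq(0L, 255L, by = 51L),
                                b = seq(0L, 255L, by = 51L)))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  if (n > nrow(grid)) stop("too many regions for distinct palette colours",
                           call. = FALSE)
  grid[base::sample(nrow(grid), n), , drop = FALSE]
}

#' Analytic voxel counts for the synthetic segmentation
#'
#' Closed-form label histogram of [make_synthetic_atlas()]'s segmentation:
#' label `k` occupies box `k` minus box `k + 1`.
#'
#' @inheritParams make_synthetic_atlas
#' @return Named numeric vector of counts for labels `0..n_regions`.
#' @export
synthetic_label_counts <- function(dims, n_regions) {
  dims <- as.integer(check_atlas_dims(dims))
  box_vol <- function(k) {
    lo <- floor(dims * k / (2 * (n_regions + 1)))
    prod(pmax(dims - 2 * lo, 0))
  }
  vols <- vapply(seq_len(n_regions), box_vol, numeric(1))
  counts <- c(prod(dims) - vols[1],
              if (n_regions > 1) vols[-n_regions] - vols[-1],
              vols[n_regions])
  stats::setNames(counts, 0:n_regions)
}
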