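#' Propagation configuration
#'
#' Controls how anchorings are estimated for unanchored sections.
#'
#' @param default_axis Sectioning axis assumed for a fresh series:
#'   `"coronal"` (default), `"sagittal"` or `"horizontal"`.
#' @param default_spacing Voxels of plane translation per unit of
#'   serial-number difference; used only when a single verified anchoring
#'   exists. When `NULL` and `atlas_dims` is supplied, defaults to
#'   `extent / (N + 1)` along the default axis (mirroring the even initial
#'   distribution of an `N`-section series).
#' @param atlas_dims Optional atlas grid dimensions `(Nx, Ny, Nz)`; enables
#'   the spacing default above and clamps extrapolated planes so their
#'   centres stay inside the atlas bounding box.
#' @return A list of class `propagation_config`.
#' @export
propagation_config <- function(default_axis = c("coronal", "sagittal",
                                                "horizontal"),
                               default_spacing = NULL, atlas_dims = NULL) {
  default_axis <- match.arg(default_axis)
  if (!is.null(default_spacing) && default_spacing <= 0) {
    stop("default_spacing must be positive", call. = FALSE)
  }
  if (!is.null(atlas_dims)) atlas_dims <- check_atlas_dims(atlas_dims)
  structure(list(default_axis = default_axis,
                 default_spacing = default_spacing,
                 atlas_dims = atlas_dims),
            class = "propagation_config")
}

axis_index <- function(axis) switch(axis, sagittal = 1L, coronal = 2L,
                                    horizontal = 3L)

#' Evenly distribute a fresh series through the atlas
#'
#' Before any section has been anchored, the `N` sections of a series are
#' given an initial distribution: evenly spaced default planes along the
#' sectioning axis, the section ranked `k` (by ascending serial number)
#' placed at `(N - k + 0.5) / N` of the axis extent — so for a coronal
#' series the first section sits most anterior. All anchorings are marked
#' `"estimated"`.
#'
#' @param s A [section_series()] (any existing anchorings are replaced).
#' @param atlas_dims Atlas grid dimensions `(Nx, Ny, Nz)`.
#' @param cfg A [propagation_config()].
#' @return The series with every slice carrying an estimated anchoring.
#' @export
initial_distribution <- function(s, atlas_dims, cfg = propagation_config()) {
  stopifnot(inherits(s, "section_series"))
  if (nrow(s) == 0) stop("cannot distribute an empty series", call. = FALSE)
  d <- check_atlas_dims(atlas_dims)
  ax <- axis_index(cfg$default_axis)
  n <- nrow(s)
  for (k in seq_len(n)) {
    pos <- (n - k + 0.5) / n * d[ax]
    a <- default_plane(cfg$default_axis, pos, d)
    s <- set_slice_anchoring(s, s$nr[k], a, status = "estimated")
  }
  s
}

#' Propagate verified anchorings across a series
#'
#' Re-estimates the anchoring of every non-verified section from the
#' user-verified ones; verified sections are never modified, so evaluating
#' the scheme at a verified serial number reproduces that anchoring
#' bit-for-bit, and running propagation twice is a no-op.
#'
#' The scheme interpolates the nine anchoring components `(o, u, v)`
#' linearly in the serial number: a section with `nr = s` strictly between
#' verified sections `a < s < b` gets
#' `(1 - t) * anchoring_a + t * anchoring_b` with `t = (s - a)/(b - a)`.
#' Serial-number gaps are respected — `t` uses `nr`, not list rank, since
#' section sampling is given by the serial numbers. Before the first and
#' after the last verified section, the two nearest verified anchorings
#' are extrapolated linearly (when `cfg$atlas_dims` is known, the
#' extrapolated plane is translated so its centre stays inside the atlas
#' bounding box). With exactly one verified section, `u` and `v` are
#' copied and `o` is translated along the plane unit normal by
#' `(s - a) * default_spacing`. All estimates are marked `"estimated"`.
#'
#' Componentwise interpolation reproduces endpoints exactly and, for small
#' angular differences between anchors, approximates interpolation of
#' position, scale and tilt; it is a documented approximation for large
#' angle gaps.
#'
#' @param s A [section_series()] with at least one verified anchoring.
#' @param cfg A [propagation_config()].
#' @return The series with estimates filled in.
#' @export
propagate_series <- function(s, cfg = propagation_config()) {
  stopifnot(inherits(s, "section_series"))
  ver <- which(s$status == "verified" & !is.na(s$ox))
  if (length(ver) == 0) {
    stop("no verified anchorings to propagate from; ",
         "use initial_distribution() for a fresh series", call. = FALSE)
  }
  vnr <- s$nr[ver]
  vmat <- as.matrix(s[ver, anchoring_cols(), drop = FALSE])
  todo <- setdiff(seq_len(nrow(s)), ver)
  for (i in todo) {
    snr <- s$nr[i]
    if (length(ver) == 1L) {
      comp <- vmat[1, ]
      a0 <- anchoring(comp[1:3], comp[4:6], comp[7:9])
      spacing <- cfg$default_spacing
      if (is.null(spacing)) {
        if (is.null(cfg$atlas_dims)) {
          stop("a single verified anchoring needs default_spacing ",
               "(or atlas_dims) in the propagation config", call. = FALSE)
        }
        spacing <- cfg$atlas_dims[axis_index(cfg$default_axis)] / (nrow(s) + 1)
      }
      o <- a0$o + (snr - vnr[1]) * spacing * anchoring_normal(a0)
      est <- c(o, a0$u, a0$v)
    } else {
      # bracketing pair, or the two nearest verified anchors at the ends
      hi <- findInterval(snr, vnr)
      if (hi == 0) {
        ia <- 1L; ib <- 2L
      } else if (hi >= length(vnr)) {
        ia <- length(vnr) - 1L; ib <- length(vnr)
      } else {
        ia <- hi; ib <- hi + 1L
      }
      t <- (snr - vnr[ia]) / (vnr[ib] - vnr[ia])
      est <- (1 - t) * vmat[ia, ] + t * vmat[ib, ]
      extrapolated <- snr < vnr[1] || snr > vnr[length(vnr)]
      if (extrapolated && !is.null(cfg$atlas_dims)) {
        est <- clamp_center(est, cfg$atlas_dims)
      }
    }
    s <- set_slice_anchoring(s, snr,
                             anchoring(est[1:3], est[4:6], est[7:9]),
                             status = "estimated")
  }
  s
}

# translate a plane so its centre lies inside [0, dims - 1]
clamp_center <- function(comp, dims) {
  o <- comp[1:3]; u <- comp[4:6]; v <- comp[7:9]
  center <- o + (u + v) / 2
  shift <- pmin(pmax(center, 0), dims - 1) - center
  c(o + shift, u, v)
}

#' Drop estimated anchorings from a series
#'
#' Clears every `"estimated"` anchoring so propagation can be recomputed
#' from the verified set alone; verified slices are untouched.
#'
#' @param s A [section_series()].
#' @return The series with estimated slices unanchored.
#' @export
restore_estimates <- function(s) {
  stopifnot(inherits(s, "section_series"))
  est <- s$status == "estimated"
  if (any(est)) s[est, anchoring_cols()] <- NA_real_
  s
}
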