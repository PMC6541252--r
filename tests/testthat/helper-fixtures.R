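# Shared fixtures: the published example descriptors and random-geometry
# generators used by the property-style tests.

example_xml_path <- function() {
  system.file("extdata", "example_series.xml", package = "atlasanchor")
}

example_json_path <- function() {
  system.file("extdata", "example_series.json", package = "atlasanchor")
}

# anchoring of slice nr 2 in the example descriptor
example_anchoring_2 <- function() {
  anchoring(o = c(312.2, 533.8, 218.4),
            u = c(-185.7, -35.5, 6.6),
            v = c(-4.6, -7.5, -171.4))
}

# a random non-degenerate anchoring; components in plausible voxel ranges
random_anchoring <- function() {
  repeat {
    a <- anchoring(o = stats::runif(3, -50, 550),
                   u = stats::runif(3, -300, 300),
                   v = stats::runif(3, -300, 300))
    n <- a$u[c(2, 3, 1)] * a$v[c(3, 1, 2)] - a$u[c(3, 1, 2)] * a$v[c(2, 3, 1)]
    if (sqrt(sum(n^2)) > 1e-3) return(a)
  }
}

# direct array-extraction oracle for an axis-aligned full-extent plane:
# row j of the plate samples the volume at descending coordinate N - j along
# the flipped axis, so the top row (j = 0, coordinate N) falls outside the
# grid and is background under the x/w weight convention
extract_plane_oracle <- function(arr, orientation, pos) {
  plane <- switch(orientation,
    coronal    = arr[, pos + 1, ],          # Nx x Nz -> flip z
    sagittal   = arr[pos + 1, , ],          # Ny x Nz -> flip z
    horizontal = arr[, , pos + 1])          # Nx x Ny -> flip y
  m <- t(plane)                             # rows = flipped axis
  n <- nrow(m)
  out <- rbind(matrix(0, 1, ncol(m)), m[n:2, , drop = FALSE])
  storage.mode(out) <- storage.mode(arr)
  out
}

# small series around the two published anchorings plus an unanchored slice
example_series_with_gap <- function() {
  s <- read_series_xml(example_xml_path())
  extra <- tibble::tibble(filename = "sampleID_s005.png", nr = 5L,
                          width = 24000, height = 18000)
  section_series(dplyr::bind_rows(tibble::as_tibble(s), extra),
                 name = series_name(s))
}
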