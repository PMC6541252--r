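test_that("native plate dimensions round the anchoring edge lengths", {
  expect_identical(native_slice_dims(example_anchoring_2()),
                   c(c_w = 189L, c_h = 172L))
  ax <- anchoring(c(0, 0, 0), c(100, 0, 0), c(0, 0, 50))
  expect_identical(native_slice_dims(ax), c(c_w = 100L, c_h = 50L))
  tiny <- anchoring(c(0, 0, 0), c(0.2, 0, 0), c(0, 0, 5))
  expect_identical(native_slice_dims(tiny)[["c_w"]], 1L)
  expect_error(native_slice_dims(anchoring(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1))),
               "zero-length")
})

test_that("axis-aligned plates equal direct array extraction bit-for-bit", {
  d <- c(16, 20, 12)
  atl <- make_synthetic_atlas(d, 3, seed = 9)
  for (vol in list(atl$segmentation, atl$template)) {
    sl_c <- render_slice(vol, default_plane("coronal", 10, d), d[1], d[3])
    expect_identical(unname(sl_c$pixels),
                     unname(extract_plane_oracle(vol$data, "coronal", 10)))
    sl_s <- render_slice(vol, default_plane("sagittal", 7, d), d[2], d[3])
    expect_identical(unname(sl_s$pixels),
                     unname(extract_plane_oracle(vol$data, "sagittal", 7)))
    sl_h <- render_slice(vol, default_plane("horizontal", 5, d), d[1], d[2])
    expect_identical(unname(sl_h$pixels),
                     unname(extract_plane_oracle(vol$data, "horizontal", 5)))
  }
})

test_that("constant volumes give constant plates; planes outside give background", {
  v <- atlas_volume(array(4.5, c(8, 8, 8)), "template")
  a <- anchoring(c(1, 6, 6), c(5, -2, 0), c(0, -2, -5))
  sl <- render_slice(v, a, 10, 10)
  expect_true(all(sl$pixels == 4.5))
  far <- anchoring(c(1000, 1000, 1000), c(5, 0, 0), c(0, 0, -5))
  expect_true(all(render_slice(v, far, 5, 5)$pixels == 0))
})

test_that("image coordinates scale onto the plate axis by axis", {
  expect_identical(image_to_slice_coords(500, 0, 1000, 800, 200, 160),
                   c(c_x = 100, c_y = 0))
  expect_identical(image_to_slice_coords(0, 0, 1000, 800, 200, 160),
                   c(c_x = 0, c_y = 0))
  last <- image_to_slice_coords(999, 799, 1000, 800, 200, 160)
  expect_identical(unname(last), c(999 * 200 / 1000, 799 * 160 / 800))
  expect_true(last[["c_x"]] < 200 && last[["c_y"]] < 160)
})

test_that("flat encoding matches the hand-encoded byte layout", {
  grid <- matrix(1:6, nrow = 2, byrow = TRUE)  # [[1,2,3],[4,5,6]]
  golden <- as.raw(c(0x01, 0, 0, 0, 3, 0, 0, 0, 2, 1, 2, 3, 4, 5, 6))
  expect_identical(write_flat(grid), golden)
  expect_identical(read_flat(golden), grid)
})

test_that("flat switches to two big-endian bytes per pixel when labels exceed 255", {
  grid <- matrix(c(300L, 1L, 65535L, 0L), nrow = 2)
  enc <- write_flat(grid)
  expect_identical(as.integer(enc[1]), 2L)
  expect_identical(length(enc), 9L + 2L * 4L)
  expect_identical(as.integer(enc[10:11]), c(1L, 44L))  # 300 = 0x012C
  expect_identical(read_flat(enc), grid)
  expect_error(write_flat(matrix(70000, 1, 1)), "2 bytes")
})

test_that("flat write/read is the identity on random grids and rejects bad buffers", {
  set.seed(13)
  for (i in 1:20) {
    hi <- if (i %% 2) 255L else 4000L
    g <- matrix(sample(0:hi, size = 12, replace = TRUE), nrow = 3)
    expect_identical(read_flat(write_flat(g)), g)
  }
  good <- write_flat(matrix(1:6, 2))
  expect_error(read_flat(good[1:8]), "no header")
  expect_error(read_flat(good[-length(good)]), "truncated")
  bad <- good; bad[1] <- as.raw(3)
  expect_error(read_flat(bad), "Bpp")
})

test_that("lookup_region names the label under a pixel", {
  d <- c(32, 40, 28)
  atl <- make_synthetic_atlas(d, 3, seed = 9)
  a <- default_plane("coronal", 20, d)
  # pixel (16, 42) of a 64x56 image -> voxel (8, 20, 7): inside box 2, not box 3
  hit <- lookup_region(atl$segmentation, atl$palette, a, 16, 42, 64, 56)
  expect_identical(hit$id, 2L)
  expect_identical(hit$name, "region_2")
  out <- lookup_region(atl$segmentation, atl$palette, a, -500, 0, 64, 56)
  expect_identical(out$id, 0L)
  expect_identical(out$name, "background")
  short_pal <- atlas_palette(0L, 0L, 0L, 0L, "background")
  expect_warning(m <- lookup_region(atl$segmentation, short_pal, a, 16, 42, 64, 56),
                 "missing from palette")
  expect_identical(m$id, 2L)
  expect_true(is.na(m$name))
})

test_that("plate lookup and direct voxel sampling agree through the coordinate map", {
  d <- c(32, 40, 28)
  atl <- make_synthetic_atlas(d, 3, seed = 9)
  a <- default_plane("coronal", 20, d)
  nd <- native_slice_dims(a)
  flat <- read_flat(write_flat(render_slice(atl$segmentation, a)))
  set.seed(14)
  w <- 64; h <- 56
  for (i in 1:50) {
    x <- sample(0:(w - 1), 1); y <- sample(0:(h - 1), 1)
    cc <- image_to_slice_coords(x, y, w, h, nd[["c_w"]], nd[["c_h"]])
    ij <- floor(cc)
    via_plate <- flat[ij[["c_y"]] + 1, ij[["c_x"]] + 1]
    # the plate pixel's own sample location reproduces its value exactly
    p_plate <- pixel_to_voxel(a, ij[["c_x"]], ij[["c_y"]],
                              nd[["c_w"]], nd[["c_h"]])
    expect_identical(via_plate,
                     as.integer(sample_volume(atl$segmentation, p_plate)))
    # and it sits within one voxel of the direct pixel-to-voxel sample, so
    # stretching the plate over the image reproduces the on-screen view
    p_direct <- pixel_to_voxel(a, x, y, w, h)
    expect_lt(max(abs(p_plate - p_direct)), 1 + 1e-9)
  }
})

test_that("export writes the predicted file set with consistent artifacts", {
  d <- c(16, 20, 12)
  atl <- make_synthetic_atlas(d, 2, seed = 15)
  s <- section_series(tibble::tibble(
    filename = c("a_s001.png", "a_s002.png"), nr = 1:2,
    width = 100, height = 80), name = "t")
  s <- initial_distribution(s, d)
  out <- withr::local_tempdir()
  written <- suppressMessages(
    export_series(s, list(atl$template, atl$segmentation),
                  palette = atl$palette, out_root = out,
                  timestamp = "20190101120000"))
  folder <- attr(written, "folder")
  expect_identical(basename(folder), "Slices-20190101120000")
  expect_setequal(basename(written), c(
    "a_s001.png-template.png", "a_s002.png-template.png",
    "a_s001.png-segmentation.png", "a_s002.png-segmentation.png",
    "a_s001.png-segmentation.flat", "a_s002.png-segmentation.flat",
    "segmentation.json"))
  # PNG pixel (i, j) equals the palette colour of the flat value at (i, j)
  flat <- read_flat(file.path(folder, "a_s001.png-segmentation.flat"))
  img <- png::readPNG(file.path(folder, "a_s001.png-segmentation.png"))
  pal <- read_palette(file.path(folder, "segmentation.json"))
  pos <- match(as.vector(flat), pal$index)
  expect_equal(as.vector(img[, , 1]) * 255, pal$red[pos], tolerance = 1e-6)
  expect_equal(as.vector(img[, , 2]) * 255, pal$green[pos], tolerance = 1e-6)
  expect_equal(as.vector(img[, , 3]) * 255, pal$blue[pos], tolerance = 1e-6)
  # collision with an existing folder gets a new suffix
  written2 <- suppressMessages(suppressWarnings(
    export_series(s, list(atl$template), out_root = out,
                  timestamp = "20190101120000")))
  expect_identical(basename(attr(written2, "folder")),
                   "Slices-20190101120000-1")
})

test_that("sections without an anchoring are skipped with a warning", {
  d <- c(16, 20, 12)
  atl <- make_synthetic_atlas(d, 2, seed = 15)
  s <- section_series(tibble::tibble(
    filename = c("a_s001.png", "a_s002.png"), nr = 1:2,
    width = 100, height = 80), name = "t")
  s <- set_slice_anchoring(s, 1, default_plane("coronal", 10, d))
  out <- withr::local_tempdir()
  expect_warning(
    written <- suppressMessages(
      export_series(s, list(atl$template), out_root = out,
                    timestamp = "20190101120001")),
    "nr 2.*skipped")
  expect_identical(basename(written), "a_s001.png-template.png")
})
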