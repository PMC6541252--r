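fresh_series <- function(n, prefix = "a_s") {
  section_series(tibble::tibble(
    filename = sprintf("%s%03d.png", prefix, seq_len(n)),
    nr = seq_len(n), width = 100, height = 80), name = "t")
}

test_that("initial distribution spaces sections evenly, first most anterior", {
  s <- initial_distribution(fresh_series(4), c(64, 80, 56))
  expect_equal(s$oy, c(70, 50, 30, 10), tolerance = 1e-12)
  expect_true(all(s$status == "estimated"))
  # all planes carry the default coronal u, v
  expect_true(all(s$ux == 64 & s$uy == 0 & s$uz == 0))
  expect_true(all(s$vx == 0 & s$vy == 0 & s$vz == -56))
  single <- initial_distribution(fresh_series(1), c(64, 80, 56))
  expect_equal(single$oy, 40, tolerance = 1e-12)
  expect_error(initial_distribution(fresh_series(1)[0, ], c(64, 80, 56)),
               "empty")
})

test_that("propagation interpolates the published anchorings at the midpoint nr", {
  s <- example_series_with_gap()   # verified nr 2 and nr 8, unanchored nr 5
  p <- propagate_series(s)
  i <- match(5L, p$nr)
  expect_lt(abs(p$ox[i] - 323.51071068230803), 1e-10)
  expect_equal(p$oy[i], (533.8 + 485.7990978550188) / 2, tolerance = 1e-12)
  expect_identical(p$status[i], "estimated")
})

test_that("verified anchorings survive propagation bit-for-bit and it is idempotent", {
  s <- example_series_with_gap()
  p1 <- propagate_series(s)
  expect_identical(as.data.frame(p1[p1$nr %in% c(2, 8), ]),
                   as.data.frame(s[s$nr %in% c(2, 8), ]))
  p2 <- propagate_series(p1)
  expect_identical(as.data.frame(p2), as.data.frame(p1))
  # propagation never touches filenames or pixel dimensions
  expect_identical(p1$filename, s$filename)
  expect_identical(p1$width, s$width)
  expect_identical(p1$height, s$height)
})

test_that("a single verified anchor translates along the plane normal", {
  s <- fresh_series(4)
  a <- default_plane("coronal", 40, c(64, 80, 56))
  s <- set_slice_anchoring(s, 1, a)
  p <- propagate_series(s, propagation_config(default_spacing = 2))
  i <- match(4L, p$nr)
  n <- anchoring_normal(a)  # (0, 1, 0) for the default coronal plane
  expect_equal(c(p$ox[i], p$oy[i], p$oz[i]), a$o + 6 * n, tolerance = 1e-12)
  expect_identical(c(p$ux[i], p$uy[i], p$uz[i]), a$u)
  expect_identical(c(p$vx[i], p$vy[i], p$vz[i]), a$v)
  # spacing default derives from the atlas extent when dims are known
  p2 <- propagate_series(s, propagation_config(atlas_dims = c(64, 80, 56)))
  expect_equal(p2$oy[match(2L, p2$nr)], 40 + 80 / 5, tolerance = 1e-12)
  expect_error(propagate_series(s), "default_spacing")
})

test_that("anchors on a linear trajectory keep every estimate on it", {
  s <- fresh_series(9)
  base <- c(o = c(5, 70, 50), u = c(60, 0, 1), v = c(0, -1, -48))
  slope <- c(o = c(0.5, -6, 0.2), u = c(0.1, 0.05, 0), v = c(0, 0.02, -0.1))
  traj <- function(nr) base + slope * nr
  for (nr in c(2L, 5L, 9L)) {
    cmp <- traj(nr)
    s <- set_slice_anchoring(s, nr, anchoring(cmp[1:3], cmp[4:6], cmp[7:9]))
  }
  p <- propagate_series(s)
  for (nr in p$nr) {
    est <- as.numeric(p[match(nr, p$nr), c("ox", "oy", "oz", "ux", "uy", "uz",
                                           "vx", "vy", "vz")])
    expect_lt(max(abs(est - traj(nr))), 1e-9)
  }
})

test_that("estimates between parallel ordered planes move monotonically", {
  s <- fresh_series(8)
  dims <- c(64, 80, 56)
  s <- set_slice_anchoring(s, 2, default_plane("coronal", 66, dims))
  s <- set_slice_anchoring(s, 7, default_plane("coronal", 22, dims))
  p <- propagate_series(s)
  expect_true(all(diff(p$oy) < 0))  # strictly decreasing along anterior axis
})

test_that("interpolation parameter uses serial numbers, not list rank", {
  # sections nr 1, 5, 9: only every 4th section imaged
  s <- section_series(tibble::tibble(
    filename = c("a_s001.png", "a_s005.png", "a_s009.png"),
    nr = c(1L, 5L, 9L), width = 100, height = 80), name = "t")
  dims <- c(64, 80, 56)
  s <- set_slice_anchoring(s, 1, default_plane("coronal", 60, dims))
  s <- set_slice_anchoring(s, 9, default_plane("coronal", 20, dims))
  p <- propagate_series(s)
  expect_equal(p$oy[match(5L, p$nr)], 40, tolerance = 1e-12)
})

test_that("extrapolated planes stay inside the atlas when dims are known", {
  dims <- c(64, 80, 56)
  s <- fresh_series(10)
  s <- set_slice_anchoring(s, 2, default_plane("coronal", 70, dims))
  s <- set_slice_anchoring(s, 3, default_plane("coronal", 50, dims))
  p_unclamped <- propagate_series(s)
  expect_gt(p_unclamped$oy[match(1L, p_unclamped$nr)], 79)  # off the front
  expect_lt(p_unclamped$oy[match(10L, p_unclamped$nr)], 0)  # off the back
  p <- propagate_series(s, propagation_config(atlas_dims = dims))
  centers <- p$oy  # coronal planes: centre y equals oy
  expect_true(all(centers >= 0 & centers <= 79))
})

test_that("restore_estimates clears only estimated anchorings", {
  s <- example_series_with_gap()
  p <- propagate_series(s)
  r <- restore_estimates(p)
  expect_true(is.na(r$ox[match(5L, r$nr)]))
  expect_identical(as.data.frame(r[r$nr %in% c(2, 8), ]),
                   as.data.frame(s[s$nr %in% c(2, 8), ]))
  expect_identical(as.data.frame(propagate_series(restore_estimates(p))),
                   as.data.frame(p))
  all_ver <- s[s$nr %in% c(2, 8), ]
  expect_identical(as.data.frame(restore_estimates(all_ver)),
                   as.data.frame(all_ver))
  expect_error(propagate_series(restore_estimates(initial_distribution(
    fresh_series(3), c(64, 80, 56)))), "initial_distribution")
})
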