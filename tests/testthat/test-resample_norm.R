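test_that("tile ratios count vine pixels per tile", {
  m <- matrix(0L, 4, 4); m[1:2, 1:2] <- 1L
  d <- tile_ratios(m, 2L)
  expect_equal(d$ratio, matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(d$npix, matrix(4L, 2, 2))
  expect_equal(tile_ratios(matrix(1L, 6, 9), 4L)$ratio,
               matrix(1, 2, 3))
  expect_equal(tile_ratios(matrix(0L, 6, 9), 4L)$ratio,
               matrix(0, 2, 3))
  expect_error(tile_ratios(m, 0L), "integer")
})

test_that("tile ratios agree with the per-pixel double-loop oracle", {
  set.seed(10)
  for (k in 1:10) {
    h <- sample(3:64, 1); w <- sample(3:64, 1); S <- sample(1:20, 1)
    m <- random_mask(h, w, runif(1, 0.1, 0.9))
    expect_equal(tile_ratios(m, S)$ratio, naive_tile_ratios(m, S))
  }
})

test_that("edge tiles use their actual pixel counts and conserve totals", {
  set.seed(11)
  for (k in 1:10) {
    h <- sample(10:80, 1); w <- sample(10:80, 1); S <- sample(3:35, 1)
    m <- random_mask(h, w, 0.4)
    d <- tile_ratios(m, S)
    expect_equal(sum(d$npix), h * w)
    expect_identical(sum(d$vine), sum(m))
    # the per-tile integer identity, with float representation rounded away
    expect_identical(as.integer(round(d$ratio * d$npix)), as.vector(d$vine))
  }
})

test_that("threshold levels reproduce the eight-gradient table exactly", {
  expect_identical(threshold_of_level(1:8),
                   c(0.88, 0.77, 0.66, 0.55, 0.44, 0.33, 0.22, 0.11))
  expect_equal(threshold_of_level(5L), 0.44)
  expect_true(all(diff(threshold_of_level(1:8)) < 0))
  expect_error(threshold_of_level(0L), "1..8")
  expect_error(threshold_of_level(9L), "1..8")
  expect_error(threshold_of_level(4.5), "1..8")
})

test_that("gradient classes partition the ratio range", {
  m <- rbind(c(0, 0.2), c(0.5, 1))
  d <- structure(list(S = 1L, ratio = m, vine = m, npix = matrix(1L, 2, 2),
                      source_dim = c(2L, 2L)), class = "distribution_map")
  g <- gradient_map(d)
  expect_equal(g$class, rbind(c("naked", "transition"),
                              c("coverage", "core")))
  # R = 0.5 sits in coverage under the default third cutpoints
  expect_equal(g$class[2, 1], "coverage")
  expect_error(gradient_map(d, c(0.7, 0.3)), "cutpoints")
  expect_error(gradient_map(d, c(0, 0.5)), "cutpoints")
  pal <- gradient_palette()
  expect_identical(rownames(pal), c("core", "coverage", "transition", "naked"))
  expect_equal(unname(pal["naked", ]), c(139, 69, 19))
})

test_that("binarization activates tiles at or above the level threshold", {
  # ratios [[1, 0], [0.5, 0.3]] at T = 5 (0.44): left column active
  m <- matrix(0L, 20, 20)
  m[1:10, 1:10] <- 1L                    # R = 1
  m[11:20, 1:10][1:50] <- 1L             # R = 0.5
  m[1:10, 11:20][1:30] <- 1L             # R = 0.3
  d <- tile_ratios(m, 10L)
  expect_equal(d$ratio, rbind(c(1, 0.3), c(0.5, 0)))
  b <- binarize_distribution(d, 5L)
  expect_equal(b$threshold, 0.44)
  expect_equal(b$active, rbind(c(TRUE, FALSE), c(TRUE, FALSE)))
  expect_true(all(binarize_distribution(tile_ratios(matrix(1L, 8, 8), 3L),
                                        1L)$active))
  expect_false(any(binarize_distribution(tile_ratios(matrix(0L, 8, 8), 3L),
                                         8L)$active))
})

test_that("active-tile count is non-decreasing in the threshold level", {
  set.seed(12)
  for (k in 1:10) {
    m <- random_mask(sample(20:60, 1), sample(20:60, 1), runif(1, 0.2, 0.7))
    for (S in c(7L, 13L, 25L)) {
      d <- tile_ratios(m, S)
      counts <- vapply(1:8, function(T) sum(binarize_distribution(d, T)$active),
                       integer(1))
      expect_true(all(diff(counts) >= 0))
    }
  }
})

test_that("block-fill reconstruction paints whole tiles and is idempotent", {
  m <- matrix(0L, 4, 4); m[1:2, 1:2] <- 1L
  b <- binarize_distribution(tile_ratios(m, 2L), 5L)
  rec <- reconstruct_pixel_map(b)
  expect_equal(dim(rec), c(4L, 4L))
  expect_identical(rec, m)
  # re-tiling the reconstruction at the same S is a fixed point
  rec2 <- reconstruct_pixel_map(binarize_distribution(tile_ratios(rec, 2L), 5L))
  expect_identical(rec2, rec)
  set.seed(13)
  mm <- random_mask(37, 51, 0.5)
  for (S in c(5L, 10L)) {
    r1 <- reconstruct_pixel_map(binarize_distribution(tile_ratios(mm, S), 6L))
    r2 <- reconstruct_pixel_map(binarize_distribution(tile_ratios(r1, S), 6L))
    expect_identical(r2, r1)
  }
  # all-active grid reconstructs to all-foreground at the source dims
  all1 <- reconstruct_pixel_map(binarize_distribution(
    tile_ratios(matrix(1L, 9, 7), 4L), 8L))
  expect_identical(all1, matrix(1L, 9, 7))
  expect_error(reconstruct_pixel_map(b, source_dim = c(5L, 4L)), "mismatch")
})

test_that("gradient reconstruction and rendering share the palette", {
  m <- matrix(0L, 4, 4); m[1:2, 1:2] <- 1L
  g <- gradient_map(tile_ratios(m, 2L))
  cls <- reconstruct_pixel_map(g)
  expect_equal(cls[1, 1], "core")
  expect_equal(cls[4, 4], "naked")
  rgb <- gradient_rgb(g)
  expect_equal(dim(rgb), c(4L, 4L, 3L))
  expect_equal(rgb[1, 1, ] * 255, unname(gradient_palette()["core", ]))
})

test_that("ratio grids survive the CSV round-trip", {
  set.seed(14)
  m <- random_mask(45, 60, 0.35)
  d <- tile_ratios(m, 13L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratio_grid(d, path)
  back <- read_ratio_grid(path)
  expect_equal(back$ratio, d$ratio)
  expect_identical(back$vine, d$vine)
  expect_equal(back$S, d$S)
  expect_equal(back$source_dim, d$source_dim)
})

test_that("sampling sizes span 35 to 90 in steps of 5", {
  s <- sampling_sizes()
  expect_length(s, 12L)
  expect_equal(s, seq(35L, 90L, 5L))
})
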