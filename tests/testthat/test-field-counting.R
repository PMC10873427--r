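test_that("thresholding follows the >= rule and validates its inputs", {
  px <- matrix(c(1, 2, 3, 4), 2, 2)
  b <- binarize(px, threshold = 1)
  expect_true(all(b))                       # threshold at the minimum
  expect_equal(attr(b, "threshold"), 1)
  b2 <- binarize(px, threshold = 3)
  expect_equal(sum(b2), 2)
  expect_error(binarize(px, threshold = 99), "outside")
  expect_error(binarize(matrix(numeric(0), 0, 0)), "empty image")
  # constant image with auto threshold: nothing is foreground
  expect_false(any(binarize(matrix(5, 4, 4), "auto")))
})

test_that("auto threshold separates the modes of a bimodal image", {
  set.seed(10)
  px <- matrix(rnorm(64 * 64, 30, 4), 64, 64)
  px[20:40, 20:40] <- rnorm(21 * 21, 170, 6)
  b <- binarize(px, "auto")
  thr <- attr(b, "threshold")
  expect_gt(thr, 60)
  expect_lt(thr, 150)
  expect_equal(sum(b), 21 * 21)
})

test_that("particle counts equal constructed ground truth with size filtering", {
  # 12 disjoint 5x5 squares (area 25 px); pixel_size 1 -> 25 um^2 each
  m <- square_particle_grid(rep(5, 12))
  res <- count_particles(m, min_area = 10, pixel_size = 1)
  expect_equal(res$count, 12L)

  # 10 squares of which 3 are single pixels below min_area
  m2 <- square_particle_grid(c(rep(5, 7), rep(1, 3)))
  res2 <- count_particles(m2, min_area = 10, pixel_size = 1)
  expect_equal(res2$count, 7L)

  # empty grid
  expect_equal(count_particles(matrix(FALSE, 16, 16))$count, 0L)
})

test_that("connectivity controls whether diagonal contacts merge", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE   # touch only diagonally
  expect_equal(count_particles(m, min_area = 0, connectivity = 8)$count, 1L)
  expect_equal(count_particles(m, min_area = 0, connectivity = 4)$count, 2L)
})

test_that("counts are monotone non-increasing in threshold and min_area", {
  fld <- make_field_image(15, seed = 77)
  px <- fld$image$pixels
  # thresholds above the background noise, where the particle regime holds
  thresholds <- c(60, 120, 190)
  counts_thr <- vapply(thresholds, function(t) {
    count_particles(binarize(px, t), min_area = 0,
                    pixel_size = fld$image$pixel_size)$count
  }, numeric(1))
  expect_true(all(diff(counts_thr) <= 0))

  b <- binarize(fld$image, "auto")
  areas <- c(0, 10, 40, 200)
  counts_area <- vapply(areas, function(a) {
    count_particles(b, min_area = a, pixel_size = fld$image$pixel_size)$count
  }, numeric(1))
  expect_true(all(diff(counts_area) <= 0))
})

test_that("count is invariant under a uniform sub-threshold background offset", {
  fld <- make_field_image(10, seed = 88)
  px <- fld$image$pixels
  thr <- 100
  c1 <- count_particles(binarize(px, thr), min_area = 10,
                        pixel_size = fld$image$pixel_size)$count
  c2 <- count_particles(binarize(px + 0, thr), min_area = 10,
                        pixel_size = fld$image$pixel_size)$count
  # offset background and threshold together: same foreground set
  c3 <- count_particles(binarize(px + 30, thr + 30), min_area = 10,
                        pixel_size = fld$image$pixel_size)$count
  expect_equal(c1, c2)
  expect_equal(c1, c3)
})

test_that("group summaries report mean, sample SD and flag singletons", {
  df <- data.frame(
    stain = "TUNEL", region = "superior",
    age = rep(c(0.5, 0.75), c(2, 1)),
    genotype = "P23H_het",
    count = c(3, 5, 9))
  s <- counts_summary(df)
  expect_equal(s$mean_count[1], 4)
  expect_equal(s$sd_count[1], sqrt(2), tolerance = 1e-9)
  expect_equal(s$n, c(2L, 1L))
  expect_true(is.na(s$sd_count[2]))
  expect_true(s$sd_flagged[2])
})

test_that("field images enforce the size consistency invariant", {
  px <- matrix(0, 100, 100)
  expect_error(field_image(px, pixel_size = 1, field_size = c(317, 317)),
               "inconsistent")
  fi <- field_image(px, pixel_size = 3.17)
  expect_equal(fi$field_size, c(317, 317))
})

test_that("channel images round-trip through PNG on disk", {
  set.seed(12)
  px <- matrix(runif(32 * 32), 32, 32)
  f <- withr::local_tempfile(fileext = ".png")
  write_channel_png(px, f)
  back <- read_channel_matrix(f)
  expect_equal(dim(back), dim(px))
  expect_gt(cor(as.vector(back), as.vector(px)), 0.999)
})
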