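test_that("every generator is bit-identical under a repeated seed", {
  expect_identical(make_fret_dataset(0.3, 1.5, 0.1, 2, noise_sd = 0.02, seed = 5),
                   make_fret_dataset(0.3, 1.5, 0.1, 2, noise_sd = 0.02, seed = 5))
  expect_identical(make_onl_series(c(a = 0.5), seed = 5),
                   make_onl_series(c(a = 0.5), seed = 5))
  expect_identical(make_coloc_pair(0.4, c(32, 32), seed = 5),
                   make_coloc_pair(0.4, c(32, 32), seed = 5))
  expect_identical(make_erg_sweep(list(r_max = 300, log_ka = 0),
                                  noise_sd = 5, seed = 5),
                   make_erg_sweep(list(r_max = 300, log_ka = 0),
                                  noise_sd = 5, seed = 5))
  expect_identical(make_field_image(5, seed = 5), make_field_image(5, seed = 5))
  expect_identical(make_qpcr_table(c(s = 0.5), ct_noise_sd = 0.3, seed = 5),
                   make_qpcr_table(c(s = 0.5), ct_noise_sd = 0.3, seed = 5))
})

test_that("generators leave the global random stream untouched", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_fret_dataset(0.3, 1.5, 0.1, 2, seed = 9))
  invisible(make_onl_series(c(a = 1), seed = 9))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("zero-noise FRET generation round-trips through the efficiency analysis", {
  ds <- make_fret_dataset(0.35, 1.2, 0.15, 2.5, noise_sd = 0, seed = 2)
  pts <- fret_points(ds$series)
  x <- pts$acceptor_donor_ratio
  expect_equal(pts$e_dm_sensitive, 0.35 * x / (1.2 + x), tolerance = 1e-12)
  expect_equal(pts$e_dm_insensitive, 0.15 * x / (2.5 + x), tolerance = 1e-12)
  expect_equal(pts$e_total, pts$e_dm_sensitive + pts$e_dm_insensitive)
  # infeasible totals are refused
  expect_error(make_fret_dataset(0.9, 0.01, 0.9, 0.01, seed = 1),
               "infeasible")
})

test_that("zero-noise ONL series equal the decay model; k = 0 stays flat", {
  ds <- make_onl_series(c(g = 0.49), noise_sd = 0, seed = 3)
  x <- ds$series$g$age
  expect_equal(ds$series$g$value, (21 - 1) * exp(-0.49 * x) + 1,
               tolerance = 1e-12)
  flat <- make_onl_series(c(g = 0), noise_sd = 0, seed = 3)
  expect_true(all(flat$series$g$value == 21))
  expect_equal(unique(ds$summary$n), 6L)
})

test_that("coloc pairs achieve the degenerate and null correlations", {
  p1 <- make_coloc_pair(1, c(64, 64), seed = 4)
  expect_equal(pearson_r(p1$a, p1$b)$r, 1)
  p0 <- make_coloc_pair(0, c(256, 256), seed = 4)
  expect_lt(abs(pearson_r(p0$a, p0$b)$r), 0.05)
})

test_that("zero-noise ERG sweeps lie exactly on the model curve", {
  truth <- list(r_max = 400, log_ka = -0.3)
  sw <- make_erg_sweep(truth, noise_sd = 0, seed = 6)
  fit <- structure(c(list(model = "standard"), truth),
                   class = "dose_response_fit")
  expect_equal(sw$sweep$amplitudes,
               predict_dose_response(fit, sw$sweep$intensities),
               tolerance = 1e-12)
})

test_that("field generator manifests record exact truth and enforce capacity", {
  fld <- make_field_image(8, seed = 7)
  expect_equal(fld$manifest$parameters$n_particles, 8)
  expect_equal(nrow(fld$manifest$parameters$centers), 8)
  blank <- make_field_image(0, seed = 7)
  b <- binarize(blank$image$pixels, max(blank$image$pixels))
  expect_equal(count_particles(b, min_area = 10,
                               pixel_size = blank$image$pixel_size)$count, 0L)
  expect_error(make_field_image(500, size = c(40, 40), seed = 7,
                                max_tries = 200),
               "capacity")
})

test_that("sub-min_area disks are excluded as configured", {
  fld <- make_field_image(6, radius_range = c(1, 1.2), noise_sd = 0, seed = 8)
  b <- binarize(fld$image, "auto")
  px_um2 <- fld$image$pixel_size^2
  small <- count_particles(b, min_area = 30, pixel_size = fld$image$pixel_size)
  all_of_them <- count_particles(b, min_area = 0,
                                 pixel_size = fld$image$pixel_size)
  expect_equal(all_of_them$count, 6L)
  expect_lt(small$count, 6L)
})

test_that("zero-noise qPCR tables reproduce the requested folds exactly", {
  tbl <- make_qpcr_table(c(a = 0.25, b = 2), ct_noise_sd = 0, seed = 9)
  expect_equal(ddct_fold(tbl$samples$a, tbl$control, "18s_rrna")$value, 0.25)
  expect_equal(ddct_fold(tbl$samples$b, tbl$control, "18s_rrna")$value, 2)
})

test_that("manifests serialize and deserialize losslessly", {
  m <- make_onl_series(c(a = 0.24, b = 0.49), seed = 11)$manifest
  f <- withr::local_tempfile(fileext = ".json")
  write_manifest(m, f)
  m2 <- read_manifest(f)
  expect_equal(m2$generator, m$generator)
  expect_equal(m2$seed, m$seed)
  expect_equal(m2$parameters$rates$a, 0.24)
  expect_equal(m2$parameters$ages, m$parameters$ages)
})
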