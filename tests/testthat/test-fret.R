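test_that("donor intensity interpolates the emission grid and enforces its range", {
  sp <- spec_from_values(c(470, 476, 482), c(10, 20, 30))
  expect_equal(donor_intensity(sp, 476), 20)        # exact grid hit
  expect_equal(donor_intensity(sp, 473), 15)        # midpoint interpolation
  expect_error(donor_intensity(sp, 500), "outside")
  expect_error(emission_spectrum(c(476, 470), c(1, 2)), "increasing")
})

test_that("dequenching decomposition matches the SDS-reference formula", {
  p <- compute_efficiencies(series_from_readouts(70, 90, 100))
  expect_equal(p$e_total, 0.30)
  expect_equal(p$e_dm_insensitive, 0.10)
  expect_equal(p$e_dm_sensitive, 0.20)

  # no dequenching, no FRET
  p0 <- compute_efficiencies(series_from_readouts(100, 100, 100))
  expect_equal(c(p0$e_total, p0$e_dm_sensitive, p0$e_dm_insensitive), c(0, 0, 0))

  # aggregate-only profile: all FRET survives DM
  pa <- compute_efficiencies(series_from_readouts(80, 80, 100))
  expect_equal(pa$e_total, 0.20)
  expect_equal(pa$e_dm_insensitive, 0.20)
  expect_equal(pa$e_dm_sensitive, 0.00)

  expect_error(compute_efficiencies(series_from_readouts(1, 1, 0)),
               "invalid reference")
})

test_that("decomposition is conservative for arbitrary readout triples", {
  set.seed(42)
  for (i in 1:50) {
    f <- runif(3, 10, 200)
    p <- compute_efficiencies(series_from_readouts(f[1], f[2], f[3]))
    # e_dm_sensitive is defined as e_total - e_dm_insensitive, exactly
    expect_identical(p$e_total - p$e_dm_insensitive - p$e_dm_sensitive, 0)
  }
})

test_that("hyperbola fit recovers noiseless parameters and honours its contracts", {
  pts <- hyperbola_points(0.40, 1.5)
  fit <- fit_fret_curve(pts, "total")
  expect_lt(abs(fit$e_max - 0.40) / 0.40, 1e-6)
  expect_lt(abs(fit$ec50 - 1.5) / 1.5, 1e-6)
  expect_equal(fit$n_points, 6L)

  # half-saturation property of the fitted curve
  expect_equal(predict_fret(fit, fit$ec50), fit$e_max / 2, tolerance = 1e-8)

  # strict monotonicity of predictions
  xs <- seq(0.01, 20, length.out = 50)
  expect_true(all(diff(predict_fret(fit, xs)) > 0))

  expect_error(fit_fret_curve(pts[1:2, ], "total"), "insufficient")
})

test_that("specificity F statistic matches a brute-force residual oracle", {
  set.seed(7)
  for (n in c(4, 6, 8, 10)) {
    x <- sort(runif(n, 0.1, 8))
    y <- 0.3 * x / (1.2 + x) + rnorm(n, 0, 0.02)
    pts <- data.frame(acceptor_donor_ratio = x, efficiency = y)
    res <- test_specificity(pts, e_max_nonspecific = 0.1)
    oracle <- brute_force_specificity_f(x, y, 0.1)
    expect_equal(res$f_statistic, oracle$f, tolerance = 1e-3)
    expect_equal(res$df_num, 1L)
    expect_equal(res$df_den, n - 2L)
    expect_gte(res$f_statistic, 0)
  }
})

test_that("a ceiling equal to the fitted Emax yields no evidence of specificity", {
  set.seed(8)
  x <- c(0.25, 0.5, 1, 2, 4, 8)
  y <- 0.3 * x / (1.5 + x) + rnorm(6, 0, 0.01)
  pts <- data.frame(acceptor_donor_ratio = x, efficiency = y)
  full <- fit_fret_curve(pts, "total")
  res <- test_specificity(pts, e_max_nonspecific = full$e_max)
  # null model can reach the unconstrained optimum: ss_null == ss_alt
  expect_equal(res$ss_null, res$ss_alt, tolerance = 1e-8)
  expect_equal(res$f_statistic, 0, tolerance = 1e-4)
  expect_gt(res$p_value, 0.95)
  expect_false(res$is_specific)
})

test_that("degrees-of-freedom contract of the specificity test", {
  pts <- hyperbola_points(0.3, 1)[1:3, ]
  expect_error(test_specificity(pts, 0.1), "degrees-of-freedom")
})

test_that("component fractions censor non-specific components", {
  fit_s <- fit_fret_curve(hyperbola_points(0.20, 1.5), "dm_sensitive")
  fit_i <- fit_fret_curve(hyperbola_points(0.10, 1.5), "dm_insensitive")

  fr <- component_fractions(fit_s, fit_i, TRUE, TRUE)
  expect_true(fr$defined)
  expect_equal(fr$fraction_sensitive, 2 / 3, tolerance = 1e-6)
  expect_equal(fr$fraction_insensitive, 1 / 3, tolerance = 1e-6)
  expect_equal(fr$fraction_sensitive + fr$fraction_insensitive, 1)

  fr2 <- component_fractions(fit_s, fit_i, FALSE, TRUE)
  expect_equal(fr2$fraction_sensitive, 0)
  expect_equal(fr2$fraction_insensitive, 1)

  fr3 <- component_fractions(fit_s, fit_i, FALSE, FALSE)
  expect_false(fr3$defined)
  expect_true(is.na(fr3$fraction_sensitive))
})

test_that("Emax and EC50 bias vanishes as noise vanishes", {
  sigmas <- c(0.02, 0.005, 0.001)
  bias <- vapply(sigmas, function(sg) {
    est <- vapply(1:30, function(s) {
      ds <- make_fret_dataset(0.4, 1.5, 0, 1, noise_sd = sg, seed = 100 + s)
      fit <- fit_fret_curve(
        data.frame(acceptor_donor_ratio = ds$points$acceptor_donor_ratio,
                   efficiency = ds$points$e_dm_sensitive), "dm_sensitive")
      fit$e_max
    }, numeric(1))
    abs(mean(est) - 0.4)
  }, numeric(1))
  expect_lt(bias[3], 0.005)
  expect_lt(bias[3], bias[1] + 0.005)
})

test_that("spectrum TSV round-trips through disk", {
  sp <- spec_from_values(seq(450, 550, 10), runif(11, 0, 100))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_tsv(sp, f)
  sp2 <- read_spectrum_tsv(f)
  expect_equal(sp2$wavelengths, sp$wavelengths)
  expect_equal(sp2$intensities, sp$intensities)
})
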