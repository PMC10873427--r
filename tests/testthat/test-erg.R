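test_that("half-saturation and asymptote properties of the standard model", {
  fit <- structure(list(model = "standard", r_max = 400, log_ka = -0.5),
                   class = "dose_response_fit")
  expect_equal(predict_dose_response(fit, 10^-0.5), 200)
  expect_equal(predict_dose_response(fit, 1e9), 400, tolerance = 1e-6)
  expect_lt(predict_dose_response(fit, 1e-12), 1e-6)
  expect_error(predict_dose_response(fit, 0), "intensity must be > 0")
})

test_that("the biphasic model nests the standard model at f in {0, 1}", {
  std <- structure(list(model = "standard", r_max = 350, log_ka = -1),
                   class = "dose_response_fit")
  bi1 <- structure(list(model = "biphasic", r_max = 350, log_ka = -1,
                        log_kb = 1.7, f = 1), class = "dose_response_fit")
  I <- 10^seq(-3, 2, length.out = 41)
  expect_equal(predict_dose_response(bi1, I), predict_dose_response(std, I))

  std_b <- structure(list(model = "standard", r_max = 350, log_ka = 1.7),
                     class = "dose_response_fit")
  bi0 <- structure(list(model = "biphasic", r_max = 350, log_ka = -1,
                        log_kb = 1.7, f = 0), class = "dose_response_fit")
  expect_equal(predict_dose_response(bi0, I), predict_dose_response(std_b, I))
})

test_that("biphasic f = 0.5 is the mean of the two single-site curves", {
  bi <- structure(list(model = "biphasic", r_max = 400, log_ka = -1,
                       log_kb = 1, f = 0.5), class = "dose_response_fit")
  sa <- structure(list(model = "standard", r_max = 400, log_ka = -1),
                  class = "dose_response_fit")
  sb <- structure(list(model = "standard", r_max = 400, log_ka = 1),
                  class = "dose_response_fit")
  I <- 10^seq(-3, 3, length.out = 25)
  expect_equal(predict_dose_response(bi, I),
               (predict_dose_response(sa, I) + predict_dose_response(sb, I)) / 2)
})

test_that("noiseless parameters are recovered and the KA < KB tie-break holds", {
  sw <- make_erg_sweep(list(r_max = 400, log_ka = -1, log_kb = 1, f = 0.6),
                       model = "biphasic",
                       intensities = 10^seq(-3, 2, length.out = 7),
                       noise_sd = 0, seed = 1)
  fit <- fit_dose_response(sw$sweep, "biphasic")
  expect_lt(abs(fit$r_max - 400) / 400, 1e-4)
  expect_lt(abs(fit$log_ka - (-1)), 1e-4)
  expect_lt(abs(fit$log_kb - 1), 1e-4)
  expect_lt(abs(fit$f - 0.6), 1e-4)
  expect_lt(fit$log_ka, fit$log_kb)
})

test_that("predictions are monotone non-decreasing in intensity", {
  sw <- make_erg_sweep(list(r_max = 300, log_ka = 0), noise_sd = 10, seed = 5)
  for (model in c("standard", "biphasic")) {
    fit <- fit_dose_response(sw$sweep, model)
    I <- 10^seq(-4, 3, length.out = 60)
    expect_true(all(diff(predict_dose_response(fit, I)) >= -1e-9))
  }
})

test_that("model selection retains the standard model when residuals match", {
  sw <- make_erg_sweep(list(r_max = 400, log_ka = 0), noise_sd = 0, seed = 2)
  sel <- select_erg_model(sw$sweep)
  expect_equal(sel$f_statistic, 0)
  expect_equal(sel$preferred$model, "standard")
})

test_that("strongly biphasic data select the biphasic model decisively", {
  sw <- make_erg_sweep(list(r_max = 400, log_ka = -1.5, log_kb = 1.2, f = 0.5),
                       model = "biphasic",
                       intensities = 10^seq(-3, 2, length.out = 9),
                       noise_sd = 2, seed = 3)
  sel <- select_erg_model(sw$sweep)
  expect_equal(sel$preferred$model, "biphasic")
  expect_lt(sel$p_value, 1e-4)
})

test_that("point-count contracts are enforced", {
  sw <- erg_sweep(c(0.01, 0.1, 1, 10), c(10, 50, 150, 200))
  expect_error(fit_dose_response(sw, "biphasic"), "insufficient")
  expect_error(select_erg_model(sw), "degrees-of-freedom")
  expect_error(erg_sweep(c(1, 0.1), c(1, 2)), "increasing")
  expect_error(erg_sweep(c(-1, 1), c(1, 2)), "positive")
})

test_that("reduced Rmax with unchanged KA is read as rod loss, not sensitivity loss", {
  # two synthetic genotypes: same KA, halved Rmax
  grid <- 10^seq(-3, 1.3, length.out = 11)
  fit_ctrl <- fit_dose_response(
    make_erg_sweep(list(r_max = 400, log_ka = -0.5), intensities = grid,
                   noise_sd = 10, seed = 21)$sweep, "standard")
  fit_mut <- fit_dose_response(
    make_erg_sweep(list(r_max = 200, log_ka = -0.5), intensities = grid,
                   noise_sd = 10, seed = 22)$sweep, "standard")
  se_ka <- sqrt(fit_ctrl$se[["log_ka"]]^2 + fit_mut$se[["log_ka"]]^2)
  se_rmax <- sqrt(fit_ctrl$se[["r_max"]]^2 + fit_mut$se[["r_max"]]^2)
  expect_lt(abs(fit_ctrl$log_ka - fit_mut$log_ka), 3 * se_ka)   # KA unchanged
  expect_gt(fit_ctrl$r_max - fit_mut$r_max, 3 * se_rmax)        # Rmax detected
})
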