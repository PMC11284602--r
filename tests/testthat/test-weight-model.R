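# Fruit-area -> fresh-weight regression.

test_that("a perfectly linear dataset is fit exactly with R^2 = 1", {
  m <- fit_weight_model(c(1, 2, 3), c(2, 4, 6))
  expect_equal(m$slope, 2, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
})

test_that("coefficients agree with the lm() oracle to 1e-10", {
  d <- generate_weight_dataset(80, slope = 2.6, intercept = 0.5, noise_sd = 3, seed = 5)
  m <- fit_weight_model(d$area_cm2, d$weight_g)
  ref <- stats::lm(weight_g ~ area_cm2, data = d)
  expect_equal(m$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(m$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(m$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
})

test_that("degenerate fits are rejected", {
  expect_error(fit_weight_model(c(2, 2, 2, 2), c(1, 2, 3, 4)),
               class = "spt_degenerate_fit")
  expect_error(fit_weight_model(c(1, 2), c(1, 2)), "at least 3")
})

test_that("prediction applies the line and floors at 0 g", {
  m <- structure(list(slope = 2, intercept = 0, r_squared = 1, n = 3,
                      sigma = 0, log_log = FALSE), class = "weight_model")
  expect_equal(predict_weight(m, 5), 10)
  m$intercept <- -1
  expect_equal(predict_weight(m, 0), 0)
  expect_error(predict_weight(m, -2))
})

test_that("round trip on synthetic data recovers the noise level", {
  d <- generate_weight_dataset(400, slope = 3, intercept = -1, noise_sd = 2, seed = 9)
  m <- fit_weight_model(d$area_cm2, d$weight_g)
  resid <- d$weight_g - predict_weight(m, d$area_cm2)
  expect_lt(abs(stats::sd(resid) - 2), 0.3)
})

test_that("R^2 is invariant to affine rescaling of areas", {
  d <- generate_weight_dataset(60, noise_sd = 2, seed = 3)
  r1 <- fit_weight_model(d$area_cm2, d$weight_g)$r_squared
  r2 <- fit_weight_model(5 * d$area_cm2 + 7, d$weight_g)$r_squared
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("parameter recovery tightens from n = 30 to n = 300", {
  err <- sapply(c(30, 300), function(n) {
    mean(sapply(1:25, function(r) {
      d <- generate_weight_dataset(n, slope = 3, intercept = -1, noise_sd = 2,
                                   seed = 1000 * n + r)
      abs(fit_weight_model(d$area_cm2, d$weight_g)$slope - 3)
    }))
  })
  expect_lt(err[2], err[1])
})

test_that("the log-log variant fits a power law", {
  set.seed(21)
  a <- runif(50, 1, 12)
  w <- 2.2 * a^1.4 * exp(rnorm(50, 0, 0.02))
  m <- fit_weight_model(a, w, log_log = TRUE)
  expect_equal(m$slope, 1.4, tolerance = 0.05)
  expect_equal(exp(m$intercept), 2.2, tolerance = 0.1)
  expect_equal(predict_weight(m, 4), 2.2 * 4^1.4, tolerance = 0.4)
})

test_that("weight models survive a JSON round trip", {
  d <- generate_weight_dataset(40, seed = 8)
  m <- fit_weight_model(d$area_cm2, d$weight_g)
  p <- file.path(tempdir(), "wm.json")
  write_weight_model(m, p)
  m2 <- read_weight_model(p)
  expect_equal(m2$slope, m$slope, tolerance = 1e-12)
  expect_equal(m2$intercept, m$intercept, tolerance = 1e-12)
  expect_equal(predict_weight(m2, 3), predict_weight(m, 3), tolerance = 1e-12)
})
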